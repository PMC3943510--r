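# write-to-temp-then-rename: partial outputs are never left in place
.atomicWrite <- function(path, writer) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    ok <- FALSE
    tryCatch({
        writer(tmp)
        ok <- file.rename(tmp, path)
    }, finally = if (!ok && file.exists(tmp)) unlink(tmp))
    if (!ok) stop("failed to write ", path)
    invisible(path)
}

#' Run the annotate / compare / filter / summarize pipeline
#'
#' Orchestrates the full workflow over files: reads a manifest, genome,
#' variant and repeat tracks, WGBS sites and an array beta matrix; builds
#' the flags table; applies the filtering policy (optionally genotype-
#' aware); and writes the annotation export plus the any-overlap, unique-
#' category and rescue summaries. Optionally starts by generating a seeded
#' synthetic fixture into `dir` ("simulate" stage). All outputs are
#' written atomically (write-to-temp-then-rename), and a run manifest JSON
#' records the command, configuration snapshot, input digests, package
#' version, seed and output paths; reruns with unchanged inputs and
#' configuration produce identical annotation digests.
#'
#' @param dir directory holding (or receiving, with `simulate = TRUE`) the
#'   standard input files `manifest.csv`, `genome.fa`, `variants.vcf`,
#'   `repeats.bed`, `wgbs.bedgraph`, `betas.csv`, `genotypes.tsv`.
#' @param out_dir output directory (default `dir`).
#' @param config a [FilterConfig-class].
#' @param simulate generate the fixture first.
#' @param seed seed for the simulate stage.
#' @param use_genotypes apply [genotypeOverride()] when genotype calls are
#'   present.
#' @param fixture_config [fixtureConfig()] overriding the default toy
#'   shape for the simulate stage (its seed is replaced by `seed`).
#' @return invisibly, a list with `flags`, `decisions`, `paired`,
#'   `summary`, `rescues` and `run_manifest`.
#' @export
runPipeline <- function(dir, out_dir = dir, config = filterConfig(),
                        simulate = FALSE, seed = 1L, use_genotypes = FALSE,
                        fixture_config = NULL) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (simulate) {
        fc <- if (is.null(fixture_config)) fixtureConfig(seed = seed) else
            modifyList(fixture_config, list(seed = as.integer(seed)))
        class(fc) <- "FixtureConfig"
        writeFixture(generateFixture(fc), dir)
    }
    inputs <- c(manifest = file.path(dir, "manifest.csv"),
                genome = file.path(dir, "genome.fa"),
                variants = file.path(dir, "variants.vcf"),
                repeats = file.path(dir, "repeats.bed"),
                wgbs = file.path(dir, "wgbs.bedgraph"),
                betas = file.path(dir, "betas.csv"))
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("missing pipeline inputs: ",
             paste(missing, collapse = ", "))

    probes <- readManifest(inputs[["manifest"]])
    genome <- .asGenome(inputs[["genome"]])
    bsg <- bisulfiteConvert(genome, sourceId = basename(inputs[["genome"]]))
    variants <- readVariants(inputs[["variants"]])
    repeats <- readRepeats(inputs[["repeats"]])
    sites <- readWgbsSites(inputs[["wgbs"]],
                           min_coverage = config@min_wgbs_coverage)
    betas <- readBetaMatrix(inputs[["betas"]])
    paired <- pairProbeWgbs(probes, sites, betas)

    flags <- annotateProbes(probes, bsg, repeats, variants, genome,
                            paired = paired,
                            unknown_threshold = config@unknown_threshold)
    decisions <- applyFilter(flags, config)
    gt_path <- file.path(dir, "genotypes.tsv")
    if (use_genotypes && file.exists(gt_path)) {
        genotypes <- utils::read.table(gt_path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
        decisions <- genotypeOverride(decisions, flags, probes, genotypes)
    }
    summary <- summarizeUnique(flags, decisions)
    rescues <- rescueReport(flags, decisions)
    any_overlap <- summarizeAnyOverlap(flags)

    out <- c(annotations = file.path(out_dir, "annotations.csv"),
             summary_unique = file.path(out_dir, "summary_unique.csv"),
             summary_any = file.path(out_dir, "summary_any_overlap.csv"),
             rescues = file.path(out_dir, "rescues.csv"))
    .atomicWrite(out[["annotations"]], function(p)
        exportAnnotations(flags, decisions, p))
    .atomicWrite(out[["summary_unique"]], function(p)
        utils::write.csv(summary$categories, p, row.names = FALSE))
    .atomicWrite(out[["summary_any"]], function(p)
        utils::write.csv(any_overlap, p, row.names = FALSE))
    .atomicWrite(out[["rescues"]], function(p)
        utils::write.csv(rescues, p, row.names = FALSE))

    run_manifest <- list(
        command = "runPipeline",
        tool = "probeQC",
        version = as.character(utils::packageVersion("probeQC")),
        seed = if (simulate) seed else NULL,
        config = list(preset = config@preset,
                      drop_multimap = config@drop_multimap,
                      drop_repeat = config@drop_repeat,
                      drop_indel = config@drop_indel,
                      drop_snp_at_cpg = config@drop_snp_at_cpg,
                      drop_typeI_body_snp = config@drop_typeI_body_snp,
                      drop_typeII_body_snp = config@drop_typeII_body_snp,
                      bisokay_rescue = config@bisokay_rescue,
                      unknown_threshold = config@unknown_threshold,
                      min_wgbs_coverage = config@min_wgbs_coverage),
        input_digests = as.list(tools::md5sum(inputs)),
        output_paths = as.list(out),
        output_digests = as.list(tools::md5sum(out)))
    .atomicWrite(file.path(out_dir, "run_manifest.json"), function(p)
        jsonlite::write_json(run_manifest, p, auto_unbox = TRUE,
                             pretty = TRUE, null = "null"))
    invisible(list(flags = flags, decisions = decisions, paired = paired,
                   summary = summary, rescues = rescues,
                   any_overlap = any_overlap,
                   run_manifest = run_manifest))
}
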