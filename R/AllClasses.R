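#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ProbeSet: a validated HM450K-style probe manifest
#'
#' Holds one row per array probe: identity, Infinium chemistry, genomic
#' anchor (the 1-based forward-strand position of the C of the interrogated
#' CpG), strand, and the 50-mer probe sequence. Rows are validated on
#' construction; see [readManifest()] for the file-level entry point that
#' collects row-level diagnostics instead of failing wholesale.
#'
#' @slot probeData a `DataFrame` with columns `probe_id`, `design_type`
#'   (`"I"` or `"II"`), `chrom`, `cpg_pos`, `strand` (`"+"`/`"-"`),
#'   `probe_seq` (50 characters over `A`, `C`, `G`, `T`, `R`; `R` only in
#'   type II probes) and optionally `source_seq`.
#'
#' @seealso [probeFootprints()], [verifyProbes()]
#' @exportClass ProbeSet
setClass("ProbeSet", representation(probeData = "DataFrame"))

.validProbeSet <- function(object) {
    pd <- object@probeData
    need <- c("probe_id", "design_type", "chrom", "cpg_pos", "strand",
              "probe_seq")
    msgs <- character(0)
    miss <- setdiff(need, colnames(pd))
    if (length(miss))
        return(paste("missing probe columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(pd$probe_id))
        msgs <- c(msgs, "duplicated probe_id values")
    if (!all(pd$design_type %in% c("I", "II")))
        msgs <- c(msgs, "design_type must be 'I' or 'II'")
    if (!all(pd$strand %in% c("+", "-")))
        msgs <- c(msgs, "strand must be '+' or '-'")
    if (any(!is.na(pd$cpg_pos) & pd$cpg_pos < 1))
        msgs <- c(msgs, "cpg_pos must be >= 1")
    if (any(nchar(pd$chrom) == 0))
        msgs <- c(msgs, "chrom must be nonempty")
    if (any(nchar(pd$probe_seq) != 50L))
        msgs <- c(msgs, "probe_seq must be exactly 50 characters")
    if (any(grepl("[^ACGTR]", pd$probe_seq)))
        msgs <- c(msgs, "probe_seq letters must be in {A,C,G,T,R}")
    bad_r <- grepl("R", pd$probe_seq) & pd$design_type == "I"
    if (any(bad_r))
        msgs <- c(msgs, "degenerate R bases are only allowed in type II probes")
    if (length(msgs)) msgs else TRUE
}
setValidity("ProbeSet", .validProbeSet)

#' Construct a ProbeSet from a data frame of probe records
#'
#' @param probes a `data.frame` or `DataFrame` with columns `probe_id`,
#'   `design_type`, `chrom`, `cpg_pos`, `strand`, `probe_seq`, and
#'   optionally `source_seq`.
#' @return a validated [ProbeSet-class] object.
#' @examples
#' ps <- ProbeSet(data.frame(
#'     probe_id = "cg0001", design_type = "I", chrom = "chr1",
#'     cpg_pos = 1001L, strand = "+",
#'     probe_seq = paste(rep("ACGTA", 10), collapse = "")))
#' length(ps)
#' @export
ProbeSet <- function(probes) {
    pd <- S4Vectors::DataFrame(probes)
    pd$probe_id <- as.character(pd$probe_id)
    pd$design_type <- as.character(pd$design_type)
    pd$chrom <- as.character(pd$chrom)
    pd$cpg_pos <- as.integer(pd$cpg_pos)
    pd$strand <- as.character(pd$strand)
    pd$probe_seq <- toupper(as.character(pd$probe_seq))
    new("ProbeSet", probeData = pd)
}

#' @describeIn ProbeSet number of probes
#' @param x a `ProbeSet`
#' @export
setMethod("length", "ProbeSet", function(x) nrow(x@probeData))

#' @describeIn ProbeSet subset probes by index, logical mask or probe id
#' @param i index vector
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "ProbeSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i))
        i <- match(i, x@probeData$probe_id)
    initialize(x, probeData = x@probeData[i, , drop = FALSE])
})

setMethod("show", "ProbeSet", function(object) {
    pd <- object@probeData
    cat("ProbeSet with", nrow(pd), "probes",
        sprintf("(%d type I, %d type II)\n",
                sum(pd$design_type == "I"), sum(pd$design_type == "II")))
    if (nrow(pd))
        cat("  chromosomes:",
            paste(unique(pd$chrom), collapse = ", "), "\n")
})

#' BisulfiteGenome: reduced-complexity genome for uniqueness mapping
#'
#' Stores, per chromosome, the fully bisulfite-converted forward text
#' (every `C` replaced by `T`) and the converted reverse-complement text
#' (reverse-complement first, then `C` to `T`). Methylation-blind by
#' construction: after full conversion neither text contains a `C`, so a
#' probe query with CpG wildcards matches regardless of methylation state.
#'
#' @slot forward `DNAStringSet` of converted forward chromosome texts.
#' @slot reverse `DNAStringSet` of converted reverse-complement texts.
#' @slot sourceId character, identifier of the source genome.
#' @seealso [bisulfiteConvert()], [countGenomicHits()]
#' @exportClass BisulfiteGenome
setClass("BisulfiteGenome", representation(
    forward = "DNAStringSet", reverse = "DNAStringSet",
    sourceId = "character"))

setValidity("BisulfiteGenome", function(object) {
    msgs <- character(0)
    if (!identical(names(object@forward), names(object@reverse)))
        msgs <- c(msgs, "forward and reverse texts must share chromosome names")
    if (!identical(Biostrings::width(object@forward),
                   Biostrings::width(object@reverse)))
        msgs <- c(msgs, "forward and reverse texts must have equal lengths")
    freq <- Biostrings::letterFrequency(object@forward, "C")
    if (length(freq) && any(freq > 0))
        msgs <- c(msgs, "converted forward text still contains C")
    freq <- Biostrings::letterFrequency(object@reverse, "C")
    if (length(freq) && any(freq > 0))
        msgs <- c(msgs, "converted reverse text still contains C")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "BisulfiteGenome", function(object) {
    cat("BisulfiteGenome:", length(object@forward), "chromosomes,",
        sum(as.numeric(Biostrings::width(object@forward))), "bp",
        sprintf("(source: %s)\n", object@sourceId))
})

#' FilterConfig: keep/discard policy for the probe-filtering workflow
#'
#' Encodes which genomic factors force removal of a probe, the rescue rules,
#' and the thresholds used by the WGBS comparison. Study-type presets expand
#' deterministically:
#'
#' * `default`: drop multimapping, repeat-overlapping, CpG-SNP and type I
#'   body-SNP probes; keep INDEL-overlapping and type II body-SNP probes;
#'   bisulfite-okay body SNPs never count.
#' * `population`: as `default` but INDEL-overlapping probes are dropped
#'   (prudent for population-wide studies without genotypes).
#' * `cell_line`: as `default` but CpG-SNP probes are kept (genetically
#'   homogeneous material).
#' * `conservative`: every factor drops, type II body SNPs included, and the
#'   bisulfite-okay rescue is disabled.
#'
#' @slot drop_multimap,drop_repeat,drop_indel,drop_snp_at_cpg logical.
#' @slot drop_typeI_body_snp,drop_typeII_body_snp logical.
#' @slot bisokay_rescue logical; when `TRUE`, body SNPs that are invisible in
#'   bisulfite space do not count toward the body-SNP reasons.
#' @slot unknown_threshold numeric; absolute array-vs-WGBS beta difference
#'   above which a probe is flagged as affected by unknown factors.
#' @slot min_wgbs_coverage integer; minimum WGBS read support per site.
#' @slot min_sd_report numeric; SD floor used when reporting per-probe SD
#'   density summaries.
#' @slot preset character; the preset this configuration was derived from.
#' @seealso [filterConfig()], [applyFilter()]
#' @exportClass FilterConfig
setClass("FilterConfig", representation(
    drop_multimap = "logical", drop_repeat = "logical",
    drop_indel = "logical", drop_snp_at_cpg = "logical",
    drop_typeI_body_snp = "logical", drop_typeII_body_snp = "logical",
    bisokay_rescue = "logical",
    unknown_threshold = "numeric", min_wgbs_coverage = "integer",
    min_sd_report = "numeric", preset = "character"))

setValidity("FilterConfig", function(object) {
    msgs <- character(0)
    if (object@unknown_threshold < 0 || object@unknown_threshold > 1)
        msgs <- c(msgs, "unknown_threshold must be in [0, 1]")
    if (object@min_sd_report < 0 || object@min_sd_report > 1)
        msgs <- c(msgs, "min_sd_report must be in [0, 1]")
    if (object@min_wgbs_coverage < 0)
        msgs <- c(msgs, "min_wgbs_coverage must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Build a FilterConfig from a preset with optional overrides
#'
#' @param preset one of `"default"`, `"population"`, `"cell_line"`,
#'   `"conservative"`; see [FilterConfig-class] for the expansions.
#' @param ... named overrides of individual slots, e.g. `drop_indel = TRUE`.
#' @return a [FilterConfig-class] object.
#' @examples
#' filterConfig("population")
#' filterConfig("default", drop_repeat = FALSE)
#' @export
filterConfig <- function(preset = c("default", "population", "cell_line",
                                    "conservative"), ...) {
    preset <- match.arg(preset)
    base <- list(drop_multimap = TRUE, drop_repeat = TRUE,
                 drop_indel = FALSE, drop_snp_at_cpg = TRUE,
                 drop_typeI_body_snp = TRUE, drop_typeII_body_snp = FALSE,
                 bisokay_rescue = TRUE, unknown_threshold = 0.3,
                 min_wgbs_coverage = 5L, min_sd_report = 0.10)
    base <- switch(preset,
        default = base,
        population = modifyList(base, list(drop_indel = TRUE)),
        cell_line = modifyList(base, list(drop_snp_at_cpg = FALSE)),
        conservative = modifyList(base, list(
            drop_indel = TRUE, drop_typeII_body_snp = TRUE,
            bisokay_rescue = FALSE)))
    over <- list(...)
    bad <- setdiff(names(over), names(base))
    if (length(bad))
        stop("unknown FilterConfig fields: ", paste(bad, collapse = ", "))
    base <- modifyList(base, over)
    base$min_wgbs_coverage <- as.integer(base$min_wgbs_coverage)
    do.call(new, c(list("FilterConfig", preset = preset), base))
}

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig (preset:", object@preset, ")\n")
    drops <- c(multimap = object@drop_multimap, repeat_ = object@drop_repeat,
               indel = object@drop_indel, snp_at_cpg = object@drop_snp_at_cpg,
               typeI_body = object@drop_typeI_body_snp,
               typeII_body = object@drop_typeII_body_snp)
    cat("  drops:", paste(names(drops)[drops], collapse = ", "), "\n")
    cat("  bisulfite-okay rescue:", object@bisokay_rescue,
        "| unknown threshold:", object@unknown_threshold,
        "| min WGBS coverage:", object@min_wgbs_coverage, "\n")
})
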