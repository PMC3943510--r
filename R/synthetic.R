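#' Configuration for the synthetic fixture generator
#'
#' Describes a toy study: a random genome, a probe manifest whose 50-mers
#' are genuine footprints of that genome, variant and repeat tracks with
#' known per-probe category labels, single-sample WGBS read counts, and a
#' probe-by-sample array beta matrix with category-specific noise. One
#' global seed fixes all randomness; every track derives a labeled sub-seed
#' so adding one track does not perturb the others.
#'
#' Noise model: true betas come from a two-component Beta mixture with
#' modes near 0 and 1 (the bimodality of genome-wide methylation); WGBS
#' betas are binomial draws at Poisson coverage (a digital measurement);
#' array betas are the true beta plus clamped Gaussian noise (an analog
#' measurement), with category-specific extra noise. Probes with a
#' homozygous-alternate SNP at the interrogated C collapse to an array beta
#' near `cpg_snp_homalt_beta`, emulating a destroyed CpG.
#'
#' @param seed integer master seed.
#' @param n_chrom,chrom_len genome shape.
#' @param n_probes manifest size.
#' @param typeII_fraction fraction of type II probes (the array is roughly
#'   72% type II).
#' @param n_samples array sample count.
#' @param counts named integer vector of planted probes per category:
#'   `multimap`, `repeat`, `indel`, `cpg_snp_c`, `cpg_snp_g`, `body_snp1`,
#'   `body_snp2`, `bisokay_only`, `unknown`; the rest are clean. The
#'   default plants roughly 5% of probes in each of the major categories
#'   and 4% in the rest, scaled to `n_probes`.
#' @param background_sd array noise SD for clean probes.
#' @param category_sd named numeric vector of extra array noise SD added on
#'   top of `background_sd` per category (categories not listed get 0).
#' @param cpg_snp_homalt_beta array beta level of homozygous-alternate
#'   CpG-SNP probes (near 0).
#' @param homalt_fraction fraction of CpG-SNP probes that are homozygous
#'   alternate in the profiled sample.
#' @param coverage_mean mean WGBS coverage (Poisson).
#' @return a `FixtureConfig` list.
#' @export
fixtureConfig <- function(seed = 1L, n_chrom = 2L, chrom_len = 15000L,
                          n_probes = 150L, typeII_fraction = 0.7,
                          n_samples = 4L,
                          counts = NULL,
                          background_sd = 0.05,
                          category_sd = c(multimap = 0.05, "repeat" = 0.10,
                                          cpg_snp_c = 0.08,
                                          cpg_snp_g = 0.08,
                                          body_snp1 = 0.02,
                                          body_snp2 = 0.02),
                          cpg_snp_homalt_beta = 0.02,
                          homalt_fraction = 0.5,
                          coverage_mean = 30) {
    known <- c("multimap", "repeat", "indel", "cpg_snp_c", "cpg_snp_g",
               "body_snp1", "body_snp2", "bisokay_only", "unknown")
    if (is.null(counts)) {
        frac <- c(multimap = 0.05, "repeat" = 0.05, indel = 0.05,
                  cpg_snp_c = 0.04, cpg_snp_g = 0.04, body_snp1 = 0.05,
                  body_snp2 = 0.04, bisokay_only = 0.05, unknown = 0.04)
        counts <- pmax(1L, as.integer(round(frac * n_probes)))
        names(counts) <- names(frac)
    }
    bad <- setdiff(names(counts), known)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    if (sum(counts) > n_probes)
        stop("planted category counts exceed n_probes")
    cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                chrom_len = as.integer(chrom_len),
                n_probes = as.integer(n_probes),
                typeII_fraction = typeII_fraction,
                n_samples = as.integer(n_samples), counts = counts,
                background_sd = background_sd, category_sd = category_sd,
                cpg_snp_homalt_beta = cpg_snp_homalt_beta,
                homalt_fraction = homalt_fraction,
                coverage_mean = coverage_mean)
    structure(cfg, class = "FixtureConfig")
}

# deterministic labeled sub-seed below 2^31
.subSeed <- function(seed, label) {
    h <- 0
    for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1014741
    as.integer((abs(seed) %% 1014741) * 2111 + h)
}

.withSeed <- function(seed, label, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(.subSeed(seed, label))
    expr
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a seeded synthetic fixture with ground truth
#'
#' Builds every input the pipeline consumes, at toy scale, with known
#' per-probe category labels: genome, manifest, variant and repeat tracks,
#' WGBS methylation, array beta matrix, and sample genotypes. Identical
#' seeds produce identical fixtures byte for byte. Multimapping probes are
#' created by duplicating their genomic segment elsewhere; all other probes
#' are unique 50-mers. Planted features are confined to disjoint genomic
#' slots so each probe carries exactly the factors of its label.
#'
#' @param config a [fixtureConfig()].
#' @return a `ProbeFixture` list: `genome` (`DNAStringSet`), `probes`
#'   ([ProbeSet-class]), `variants`, `repeats` (`GRanges`), `wgbs`
#'   (data.frame of raw sites), `betas` (matrix), `genotypes`, `truth`
#'   (ground-truth data.frame) and `config`. Use [writeFixture()] to
#'   materialise files.
#' @export
generateFixture <- function(config = fixtureConfig()) {
    seed <- config$seed
    slot_w <- 110L
    anchor <- 55L

    # --- genome ----------------------------------------------------------
    chroms <- paste0("chr", seq_len(config$n_chrom))
    genome_chars <- .withSeed(seed, "genome", lapply(chroms, function(ch)
        sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE)))
    names(genome_chars) <- chroms

    # --- slot allocation -------------------------------------------------
    slots <- do.call(rbind, lapply(chroms, function(ch) {
        starts <- seq(1L, config$chrom_len - slot_w, by = slot_w)
        data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
    }))
    n_mm <- if ("multimap" %in% names(config$counts))
        config$counts[["multimap"]] else 0L
    n_decoy <- 12L
    need <- config$n_probes + n_mm + n_decoy
    if (need > nrow(slots))
        stop("infeasible planting: ", need, " slots needed, ",
             nrow(slots), " available; increase chrom_len or n_chrom")
    ord <- .withSeed(seed, "slots", sample.int(nrow(slots)))
    probe_slots <- slots[ord[seq_len(config$n_probes)], , drop = FALSE]
    copy_slots <- slots[ord[config$n_probes + seq_len(n_mm)], ,
                        drop = FALSE]
    decoy_slots <- slots[ord[config$n_probes + n_mm + seq_len(n_decoy)], ,
                         drop = FALSE]

    # --- per-probe design ------------------------------------------------
    category <- rep("clean", config$n_probes)
    k <- 0L
    for (nm in names(config$counts)) {
        cnt <- config$counts[[nm]]
        if (cnt > 0L) category[k + seq_len(cnt)] <- nm
        k <- k + cnt
    }
    category <- .withSeed(seed, "categories", sample(category))
    design_type <- .withSeed(seed, "design", ifelse(
        stats::runif(config$n_probes) < config$typeII_fraction, "II", "I"))
    strand <- .withSeed(seed, "strand",
                        sample(c("+", "-"), config$n_probes, TRUE))
    chrom <- probe_slots$chrom
    cpg_pos <- probe_slots$start + anchor
    probe_id <- sprintf("cg%06d", seq_len(config$n_probes))

    # force the interrogated CpG into the genome
    for (i in seq_len(config$n_probes)) {
        genome_chars[[chrom[i]]][cpg_pos[i]] <- "C"
        genome_chars[[chrom[i]]][cpg_pos[i] + 1L] <- "G"
    }

    start0 <- .footprintStart0(design_type, strand, cpg_pos)
    fp1 <- start0 + 1L  # 1-based first footprint base

    # --- plant variants and repeats --------------------------------------
    vlist <- list()
    het_draw <- .withSeed(seed, "avg_het",
                          stats::runif(4L * config$n_probes, 0.01, 0.49))
    het_i <- 0L
    nextHet <- function() {
        het_i <<- het_i + 1L
        het_draw[het_i]
    }
    addVar <- function(ch, pos, ref, alt, het) {
        vlist[[length(vlist) + 1L]] <<- data.frame(
            chrom = ch, pos = pos, ref = ref, alt = alt, avg_het = het,
            stringsAsFactors = FALSE)
    }
    not_bisokay_alt <- c(A = "G", C = "G", G = "A", T = "A")
    truth_body_total <- integer(config$n_probes)
    truth_body_bisokay <- integer(config$n_probes)
    truth_het <- rep(NA_real_, config$n_probes)
    rep_list <- list()

    for (i in seq_len(config$n_probes)) {
        ch <- chrom[i]; g <- genome_chars[[ch]]
        body_at <- function(off) fp1[i] + off  # positions inside footprint
        if (category[i] == "repeat") {
            rep_list[[length(rep_list) + 1L]] <- data.frame(
                chrom = ch, start0 = start0[i] + 10L, end = start0[i] + 40L,
                stringsAsFactors = FALSE)
        } else if (category[i] == "indel") {
            p <- body_at(20L)
            ref <- paste(g[p:(p + 2L)], collapse = "")
            addVar(ch, p, ref, substr(ref, 1L, 1L), nextHet())
        } else if (category[i] == "cpg_snp_c") {
            h <- nextHet(); truth_het[i] <- h
            addVar(ch, cpg_pos[i], "C", "A", h)
        } else if (category[i] == "cpg_snp_g") {
            h <- nextHet(); truth_het[i] <- h
            addVar(ch, cpg_pos[i] + 1L, "G", "A", h)
        } else if (category[i] %in% c("body_snp1", "body_snp2")) {
            offs <- if (category[i] == "body_snp1") 10L else c(10L, 25L)
            hmax <- -Inf
            for (off in offs) {
                p <- body_at(off)
                ref <- g[p]
                h <- nextHet(); hmax <- max(hmax, h)
                addVar(ch, p, ref, not_bisokay_alt[[ref]], h)
            }
            truth_body_total[i] <- length(offs)
            truth_het[i] <- hmax
        } else if (category[i] == "bisokay_only") {
            p <- body_at(12L)
            genome_chars[[ch]][p] <- "C"
            genome_chars[[ch]][p + 1L] <- "A"  # non-G downstream
            h <- nextHet(); truth_het[i] <- h
            addVar(ch, p, "C", "T", h)
            truth_body_total[i] <- 1L
            truth_body_bisokay[i] <- 1L
        }
    }

    # decoys: features in unused slots exercise the "no overlap" paths
    d <- decoy_slots
    ref1 <- genome_chars[[d$chrom[1L]]][d$start[1L] + 30L]
    addVar(d$chrom[1L], d$start[1L] + 30L, ref1,
           paste(setdiff(c("A", "C", "G", "T"), ref1)[1:2],
                 collapse = ","), 0.11)
    ref2 <- genome_chars[[d$chrom[2L]]][d$start[2L] + 30L]
    addVar(d$chrom[2L], d$start[2L] + 30L, ref2,
           setdiff(c("A", "C", "G", "T"), ref2)[1L], NA_real_)
    rep_list[[length(rep_list) + 1L]] <- data.frame(
        chrom = d$chrom[3L], start0 = d$start[3L] + 10L,
        end = d$start[3L] + 90L, stringsAsFactors = FALSE)

    # --- multimap duplication (after all sequence edits) -----------------
    mm_idx <- which(category == "multimap")
    for (j in seq_along(mm_idx)) {
        i <- mm_idx[j]
        seg <- genome_chars[[chrom[i]]][fp1[i]:(fp1[i] + 49L)]
        cch <- copy_slots$chrom[j]; cs <- copy_slots$start[j] + 30L
        genome_chars[[cch]][cs:(cs + 49L)] <- seg
    }

    genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                              character(1), collapse = ""))
    names(genome) <- chroms

    # --- probe sequences (designer rendering to bisulfite space) ---------
    probe_seq <- character(config$n_probes)
    for (i in seq_len(config$n_probes)) {
        s <- genome_chars[[chrom[i]]][fp1[i]:(fp1[i] + 49L)]
        if (strand[i] == "-")
            s <- rev(chartr("ACGT", "TGCA", s))
        probe_seq[i] <- .renderProbe(s, design_type[i])
    }

    # --- variant table ---------------------------------------------------
    variants <- if (length(vlist)) do.call(rbind, vlist) else
        data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   avg_het = numeric(0), stringsAsFactors = FALSE)
    # split the planted multi-allelic decoy like readVariants() would
    alts <- strsplit(variants$alt, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(variants)), lengths(alts))
    variants <- data.frame(chrom = variants$chrom[idx],
                           pos = variants$pos[idx],
                           ref = variants$ref[idx], alt = unlist(alts),
                           avg_het = variants$avg_het[idx],
                           stringsAsFactors = FALSE)
    variants$vtype <- ifelse(nchar(variants$ref) == 1L &
                             nchar(variants$alt) == 1L, "SNP", "INDEL")
    variants <- variants[order(variants$chrom, variants$pos), ,
                         drop = FALSE]
    rownames(variants) <- NULL

    repeats_df <- do.call(rbind, rep_list)
    fams <- .withSeed(seed, "repeat_family",
                      sample(c("AluY", "L1", "MIR", "LTR12"),
                             nrow(repeats_df), TRUE))
    repeats <- GenomicRanges::GRanges(
        repeats_df$chrom,
        IRanges::IRanges(start = repeats_df$start0 + 1L,
                         end = repeats_df$end),
        family = fams)

    # --- methylation truth and measurements ------------------------------
    comp <- .withSeed(seed, "beta_mixture", list(
        which = stats::runif(config$n_probes) < 0.5,
        lo = stats::rbeta(config$n_probes, 0.5, 5),
        hi = stats::rbeta(config$n_probes, 5, 0.5)))
    true_beta <- ifelse(comp$which, comp$lo, comp$hi)

    wgbs_cov <- .withSeed(seed, "wgbs_cov",
                          stats::rpois(config$n_probes,
                                       config$coverage_mean))
    wgbs_meth <- .withSeed(seed, "wgbs_meth",
                           stats::rbinom(config$n_probes, wgbs_cov,
                                         true_beta))
    score <- ifelse(wgbs_cov > 0L,
                    as.integer(round(100 * wgbs_meth / pmax(wgbs_cov, 1L))),
                    NA_integer_)
    wgbs <- data.frame(chrom = chrom, pos = cpg_pos, score = score,
                       coverage = wgbs_cov, stringsAsFactors = FALSE)
    wgbs <- wgbs[wgbs$coverage > 0L, , drop = FALSE]
    # decoy sites: one well covered off-probe site, one below any
    # reasonable coverage floor
    wgbs <- rbind(wgbs, data.frame(
        chrom = c(d$chrom[4L], d$chrom[5L]),
        pos = c(d$start[4L] + 40L, d$start[5L] + 40L),
        score = c(50L, 100L), coverage = c(20L, 2L),
        stringsAsFactors = FALSE))
    wgbs <- wgbs[order(wgbs$chrom, wgbs$pos), , drop = FALSE]
    rownames(wgbs) <- NULL

    # genotypes for CpG-SNP probes in the profiled sample
    is_cpg_cat <- category %in% c("cpg_snp_c", "cpg_snp_g")
    zyg <- rep(NA_character_, config$n_probes)
    zdraw <- .withSeed(seed, "zygosity", stats::runif(config$n_probes))
    zyg[is_cpg_cat] <- ifelse(
        zdraw[is_cpg_cat] < config$homalt_fraction, "hom_alt",
        ifelse(zdraw[is_cpg_cat] <
                   config$homalt_fraction +
                   (1 - config$homalt_fraction) / 2, "het", "hom_ref"))
    gt_pos <- ifelse(category == "cpg_snp_g", cpg_pos + 1L, cpg_pos)
    genotypes <- data.frame(chrom = chrom[is_cpg_cat],
                            pos = gt_pos[is_cpg_cat],
                            zygosity = zyg[is_cpg_cat],
                            stringsAsFactors = FALSE)

    # array betas: clamped Gaussian noise around truth, category-specific
    extra <- rep(0, config$n_probes)
    for (nm in names(config$category_sd))
        extra[category == nm] <- config$category_sd[[nm]]
    sd_probe <- config$background_sd + extra
    hom_alt <- !is.na(zyg) & zyg == "hom_alt"
    # shift points away from the nearer beta boundary so clamping cannot
    # swallow the planted discordance
    shift <- .withSeed(seed, "unknown_shift",
                       ifelse(true_beta > 0.5, -1, 1) *
                           stats::runif(config$n_probes, 0.35, 0.5))
    noise <- .withSeed(seed, "array_noise", matrix(
        stats::rnorm(config$n_probes * config$n_samples),
        config$n_probes, config$n_samples))
    betas <- .clamp01(true_beta + noise * sd_probe)
    unk <- category == "unknown"
    betas[unk, ] <- .clamp01(true_beta[unk] + shift[unk] +
                             noise[unk, , drop = FALSE] * 0.01)
    betas[hom_alt, ] <- .clamp01(config$cpg_snp_homalt_beta +
                                 noise[hom_alt, , drop = FALSE] * 0.01)
    dimnames(betas) <- list(probe_id,
                            sprintf("S%02d", seq_len(config$n_samples)))

    # --- ground truth ----------------------------------------------------
    covered <- wgbs_cov >= 5L
    beta_wgbs_realized <- ifelse(covered, score / 100, NA_real_)
    unknown_truth <- ifelse(covered,
                            abs(betas[, 1L] - beta_wgbs_realized) > 0.3, NA)
    truth <- data.frame(
        probe_id = probe_id, category = category,
        design_type = design_type, chrom = chrom, cpg_pos = cpg_pos,
        strand = strand, true_beta = true_beta,
        multimap = category == "multimap",
        repeat_overlap = category == "repeat",
        indel_overlap = category == "indel",
        snp_at_cpg_c = category == "cpg_snp_c",
        snp_at_cpg_g = category == "cpg_snp_g",
        body_snps_total = truth_body_total,
        body_snps_bisokay = truth_body_bisokay,
        max_avg_het = truth_het,
        zygosity = zyg,
        wgbs_covered = covered,
        unknown_factor = unknown_truth,
        stringsAsFactors = FALSE)

    probes <- ProbeSet(data.frame(
        probe_id = probe_id, design_type = design_type, chrom = chrom,
        cpg_pos = cpg_pos, strand = strand, probe_seq = probe_seq,
        stringsAsFactors = FALSE))

    structure(list(genome = genome, probes = probes, variants = variants,
                   repeats = repeats, wgbs = wgbs, betas = betas,
                   genotypes = genotypes, truth = truth, config = config),
              class = "ProbeFixture")
}

# bisulfite-space rendering of a genomic footprint as the designer would
# print it: non-CpG C fixed to T; CpG-context C retained (the wildcard
# position); for type II probes the G of each retained CpG becomes the
# degenerate R base
.renderProbe <- function(chars, design_type) {
    n <- length(chars)
    out <- chars
    i <- 1L
    while (i <= n) {
        if (out[i] == "C") {
            if (i < n && out[i + 1L] == "G") {
                if (design_type == "II") out[i + 1L] <- "R"
                i <- i + 2L
                next
            }
            out[i] <- "T"
        }
        i <- i + 1L
    }
    paste(out, collapse = "")
}

#' Write a fixture to standard files
#'
#' Materialises a [generateFixture()] result as FASTA, manifest CSV, VCF
#' (with an `AVGHET` INFO field), BED6, bedGraph (5 columns including
#' coverage), beta-matrix CSV, genotype TSV and ground-truth TSV.
#'
#' @param fixture a `ProbeFixture`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
writeFixture <- function(fixture, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
               manifest = file.path(dir, "manifest.csv"),
               variants = file.path(dir, "variants.vcf"),
               repeats = file.path(dir, "repeats.bed"),
               wgbs = file.path(dir, "wgbs.bedgraph"),
               betas = file.path(dir, "betas.csv"),
               genotypes = file.path(dir, "genotypes.tsv"),
               truth = file.path(dir, "ground_truth.tsv"))
    Biostrings::writeXStringSet(fixture$genome, paths[["genome"]])
    writeManifest(fixture$probes, paths[["manifest"]])

    v <- fixture$variants
    info <- ifelse(is.na(v$avg_het), ".",
                   sprintf("AVGHET=%.4f", v$avg_het))
    vcf_lines <- c(
        "##fileformat=VCFv4.2",
        paste0("##INFO=<ID=AVGHET,Number=1,Type=Float,",
               "Description=\"Average heterozygosity\">"),
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", sep = "\t"),
        sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", v$chrom, v$pos,
                sprintf("rs%04d", seq_len(nrow(v))), v$ref, v$alt, info))
    writeLines(vcf_lines, paths[["variants"]])

    r <- fixture$repeats
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+",
                       as.character(GenomicRanges::seqnames(r)),
                       BiocGenerics::start(r) - 1L, BiocGenerics::end(r),
                       r$family),
               paths[["repeats"]])

    w <- fixture$wgbs
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d", w$chrom, w$pos - 1L, w$pos,
                       w$score, w$coverage), paths[["wgbs"]])

    b <- data.frame(probe_id = rownames(fixture$betas), fixture$betas,
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(b, paths[["betas"]], row.names = FALSE, quote = FALSE)

    utils::write.table(fixture$genotypes, paths[["genotypes"]],
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths
}

#' Expected filtering verdicts from ground-truth labels
#'
#' An independent restatement of the decision rules, computed from the
#' generator's labels alone; it shares no code with [applyFilter()] and
#' serves as its oracle in end-to-end tests.
#'
#' @param truth ground-truth data.frame from a fixture.
#' @param config a [FilterConfig-class].
#' @return data.frame `probe_id`, `verdict`.
#' @export
expectedDecisions <- function(truth, config = filterConfig()) {
    body <- truth$body_snps_total -
        if (config@bisokay_rescue) truth$body_snps_bisokay else 0L
    discard <-
        (config@drop_multimap & truth$multimap) |
        (config@drop_repeat & truth$repeat_overlap) |
        (config@drop_indel & truth$indel_overlap) |
        (config@drop_snp_at_cpg & (truth$snp_at_cpg_c | truth$snp_at_cpg_g)) |
        (config@drop_typeI_body_snp & truth$design_type == "I" & body > 0) |
        (config@drop_typeII_body_snp & truth$design_type == "II" &
             body > 0) |
        (!is.na(truth$unknown_factor) & truth$unknown_factor)
    data.frame(probe_id = truth$probe_id,
               verdict = ifelse(discard, "discard", "keep"),
               stringsAsFactors = FALSE)
}

#' Simulate array-vs-WGBS beta pairs under the fixture noise model
#'
#' In-memory companion to [generateFixture()] for statistical power
#' studies: true betas from the bimodal mixture, WGBS betas as binomial
#' draws at Poisson coverage (conditioned on the standard 5-read floor),
#' array betas with clamped Gaussian noise of the given SD.
#'
#' @param n number of probes.
#' @param array_sd array noise SD (background 0.05; a corrupted category
#'   would use background plus its extra SD).
#' @param coverage_mean mean WGBS coverage.
#' @param seed integer seed.
#' @param prefix probe-id prefix.
#' @return a paired-beta data.frame as from [pairProbeWgbs()].
#' @export
simulatePairedBetas <- function(n, array_sd, coverage_mean = 30,
                                seed = 1L, prefix = "sim") {
    .withSeed(seed, paste0("pairs_", prefix, "_", array_sd), {
        true <- ifelse(stats::runif(n) < 0.5, stats::rbeta(n, 0.5, 5),
                       stats::rbeta(n, 5, 0.5))
        cov <- pmax(stats::rpois(n, coverage_mean), 5L)
        bw <- stats::rbinom(n, cov, true) / cov
        ba <- .clamp01(true + stats::rnorm(n, 0, array_sd))
        data.frame(probe_id = sprintf("%s%06d", prefix, seq_len(n)),
                   beta_array = ba, beta_wgbs = bw,
                   abs_diff = abs(ba - bw), signed_diff = ba - bw,
                   stringsAsFactors = FALSE)
    })
}
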