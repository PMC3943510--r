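#' Load per-base WGBS methylation sites with a coverage filter
#'
#' Accepts a bedGraph-style 5-column table (`chrom`, `start0`, `end`,
#' `score`, `coverage`; positions 0-based half-open) or a 4-column table
#' (`chrom`, `pos`, `score`, `coverage`; 1-based). Scores range 0-100 and
#' are divided by 100 into betas. Sites supported by fewer than
#' `min_coverage` reads are excluded (default 5 reads).
#'
#' @param path file path (tab-separated, no header required; a header line
#'   is auto-detected).
#' @param min_coverage minimum read support to retain a site.
#' @return data.frame `chrom`, `pos` (1-based), `beta`, `coverage`; the
#'   attribute `"n_low_coverage"` counts the excluded sites.
#' @export
readWgbsSites <- function(path, min_coverage = 5L) {
    if (!file.exists(path)) stop("WGBS file not found: ", path)
    first <- readLines(path, n = 1L)
    if (!length(first)) {
        out <- data.frame(chrom = character(0), pos = integer(0),
                          beta = numeric(0), coverage = integer(0),
                          stringsAsFactors = FALSE)
        attr(out, "n_low_coverage") <- 0L
        return(out)
    }
    header <- grepl("chrom", first, ignore.case = TRUE)
    df <- utils::read.table(path, header = header, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) == 5L) {
        df <- data.frame(chrom = as.character(df[[1]]),
                         pos = as.integer(df[[2]]) + 1L,
                         score = as.numeric(df[[4]]),
                         coverage = as.integer(df[[5]]),
                         stringsAsFactors = FALSE)
    } else if (ncol(df) == 4L) {
        df <- data.frame(chrom = as.character(df[[1]]),
                         pos = as.integer(df[[2]]),
                         score = as.numeric(df[[3]]),
                         coverage = as.integer(df[[4]]),
                         stringsAsFactors = FALSE)
    } else stop("WGBS table must have 4 or 5 columns, got ", ncol(df))
    bad <- is.na(df$score) | df$score < 0 | df$score > 100
    if (any(bad)) {
        warning(sum(bad), " WGBS records with score outside [0, 100] dropped")
        df <- df[!bad, , drop = FALSE]
    }
    low <- df$coverage < min_coverage
    out <- data.frame(chrom = df$chrom[!low], pos = df$pos[!low],
                      beta = df$score[!low] / 100,
                      coverage = df$coverage[!low], stringsAsFactors = FALSE)
    attr(out, "n_low_coverage") <- sum(low)
    out
}

#' Pair array betas with WGBS betas at the interrogated C
#'
#' Matches each probe's interrogated C (forward-strand `cpg_pos`) against
#' the surviving WGBS sites, exactly by position; no merging with the
#' symmetric reverse-strand CpG measurement unless `merge_strands = TRUE`
#' (coverage-weighted mean of the site at `cpg_pos` and `cpg_pos + 1`).
#' Duplicate WGBS rows at one position keep the higher-coverage row, with a
#' warning.
#'
#' @param probes a [ProbeSet-class].
#' @param sites WGBS sites from [readWgbsSites()].
#' @param betas single-sample array betas: a named numeric vector keyed by
#'   probe id, or a data.frame/matrix whose first column (or column
#'   `beta`) is used with probe ids as row names or a `probe_id` column.
#' @param merge_strands combine the two strand measurements of a CpG.
#' @return data.frame `probe_id`, `beta_array`, `beta_wgbs`, `abs_diff`,
#'   `signed_diff` (array minus sequencing); attribute `"unmatched"` lists
#'   probe ids without a surviving site or array beta.
#' @export
pairProbeWgbs <- function(probes, sites, betas, merge_strands = FALSE) {
    pd <- probes@probeData
    betas <- .asBetaVector(betas)
    dup <- duplicated(sites[, c("chrom", "pos")])
    if (any(dup)) {
        warning(sum(dup), " duplicate WGBS positions; keeping the ",
                "higher-coverage row")
        sites <- sites[order(sites$chrom, sites$pos, -sites$coverage), ,
                       drop = FALSE]
        sites <- sites[!duplicated(sites[, c("chrom", "pos")]), ,
                       drop = FALSE]
    }
    key <- paste(sites$chrom, sites$pos)
    idx <- match(paste(pd$chrom, pd$cpg_pos), key)
    bw <- sites$beta[idx]
    if (merge_strands) {
        idx2 <- match(paste(pd$chrom, pd$cpg_pos + 1L), key)
        w1 <- sites$coverage[idx]; w2 <- sites$coverage[idx2]
        both <- !is.na(idx) & !is.na(idx2)
        bw[both] <- (sites$beta[idx[both]] * w1[both] +
                     sites$beta[idx2[both]] * w2[both]) /
            (w1[both] + w2[both])
        only2 <- is.na(idx) & !is.na(idx2)
        bw[only2] <- sites$beta[idx2[only2]]
    }
    ba <- unname(betas[pd$probe_id])
    ok <- !is.na(bw) & !is.na(ba)
    out <- data.frame(probe_id = pd$probe_id[ok], beta_array = ba[ok],
                      beta_wgbs = bw[ok],
                      abs_diff = abs(ba[ok] - bw[ok]),
                      signed_diff = ba[ok] - bw[ok],
                      stringsAsFactors = FALSE)
    attr(out, "unmatched") <- pd$probe_id[!ok]
    out
}

.asBetaVector <- function(betas) {
    if (is.numeric(betas) && !is.null(names(betas))) return(betas)
    if (is.matrix(betas))
        return(stats::setNames(betas[, 1L], rownames(betas)))
    if (is.data.frame(betas)) {
        ids <- if (!is.null(betas$probe_id)) betas$probe_id else
            rownames(betas)
        col <- if (!is.null(betas$beta)) betas$beta else
            betas[[setdiff(colnames(betas), "probe_id")[1L]]]
        return(stats::setNames(as.numeric(col), ids))
    }
    stop("betas must be a named vector, matrix, or data.frame")
}

#' Read a probe-by-sample beta matrix from CSV
#'
#' Probe ids in the first column, one column per sample, betas in \[0, 1\]
#' with missing values allowed.
#'
#' @param path CSV path.
#' @return numeric matrix with probe ids as row names.
#' @export
readBetaMatrix <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, row.names = 1L,
                          check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    rng <- range(m, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
        stop("beta values outside [0, 1] in ", path)
    m
}

#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test
#'
#' `mode = "auto"` uses the exact distribution when both samples have at
#' most 8 observations and there are no ties, and otherwise the normal
#' approximation with tie and continuity corrections. The exact and normal
#' routes can be forced for comparison.
#'
#' @param a,b numeric samples (both nonempty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param alternative passed to the test; the package default is two-sided
#'   everywhere.
#' @return the p-value.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
#' @export
wilcoxonRankSum <- function(a, b, mode = c("auto", "exact", "normal"),
                            alternative = "two.sided") {
    mode <- match.arg(mode)
    if (!length(a) || !length(b)) stop("both samples must be nonempty")
    ties <- any(duplicated(c(a, b)))
    exact <- switch(mode,
        auto = length(a) <= 8L && length(b) <= 8L && !ties,
        exact = TRUE,
        normal = FALSE)
    if (exact && ties)
        stop("exact mode is undefined in the presence of ties")
    suppressWarnings(stats::wilcox.test(
        a, b, exact = exact, correct = TRUE,
        alternative = alternative))$p.value
}

#' Noise statistics for one probe category against the high-quality
#' background
#'
#' Computes the per-category row of the noise-assessment table: the number
#' of unique paired probes in the category, the median absolute beta
#' difference, the Pearson correlation between WGBS and array betas, and
#' the two-sided Wilcoxon rank-sum p-value of the category's absolute
#' differences against the high-quality background differences.
#'
#' @param paired paired-beta data.frame from [pairProbeWgbs()].
#' @param category_ids probe ids forming the category.
#' @param background_ids probe ids forming the high-quality background.
#' @param label category label carried into the output.
#' @return one-row data.frame `category`, `n`, `median_abs_diff`,
#'   `pearson_r`, `wilcoxon_p`; statistics are `NA` when the category has
#'   no pairs (and `pearson_r` additionally requires 3 pairs and nonzero
#'   variance on both axes).
#' @export
categoryStats <- function(paired, category_ids, background_ids,
                          label = "category") {
    cat_rows <- paired[paired$probe_id %in% category_ids, , drop = FALSE]
    bg_rows <- paired[paired$probe_id %in% background_ids, , drop = FALSE]
    n <- length(unique(cat_rows$probe_id))
    med <- if (n) stats::median(cat_rows$abs_diff) else NA_real_
    r <- NA_real_
    if (n >= 3 && stats::sd(cat_rows$beta_wgbs) > 0 &&
        stats::sd(cat_rows$beta_array) > 0)
        r <- stats::cor(cat_rows$beta_wgbs, cat_rows$beta_array)
    p <- if (n && nrow(bg_rows))
        wilcoxonRankSum(cat_rows$abs_diff, bg_rows$abs_diff) else NA_real_
    data.frame(category = label, n = n, median_abs_diff = med,
               pearson_r = r, wilcoxon_p = p, stringsAsFactors = FALSE)
}

#' Full category table of noise statistics
#'
#' Builds the standard category rows (high-quality, multimap, repeats,
#' INDELs, bisulfite-okay, SNP at CpG C / G, one body SNP, two or more
#' body SNPs, unknown factors) from a flags table, optionally split by
#' Infinium chemistry. The high-quality background row carries `NA` for its
#' own Wilcoxon p.
#'
#' @param paired paired-beta data.frame from [pairProbeWgbs()].
#' @param flags `ProbeFlags` data.frame from [annotateProbes()].
#' @param by_chemistry split categories by design type.
#' @return data.frame of [categoryStats()] rows (plus a `design_type`
#'   column when split).
#' @export
categoryTable <- function(paired, flags, by_chemistry = FALSE) {
    build <- function(fl, tag) {
        hq <- fl$probe_id[.isHighQuality(fl)]
        sets <- list(
            high_quality = hq,
            multimap = fl$probe_id[fl$multimap],
            repeats = fl$probe_id[fl$repeat_overlap],
            indels = fl$probe_id[fl$indel_overlap],
            bis_okay = fl$probe_id[fl$body_snps_total > 0 &
                                   fl$body_snps_effective == 0],
            snp_at_cpg_c = fl$probe_id[fl$snp_at_cpg_c],
            snp_at_cpg_g = fl$probe_id[fl$snp_at_cpg_g],
            snp_1 = fl$probe_id[fl$body_snps_total == 1],
            snp_2plus = fl$probe_id[fl$body_snps_total >= 2],
            unknown = fl$probe_id[!is.na(fl$unknown_factor) &
                                  fl$unknown_factor])
        rows <- lapply(names(sets), function(nm) {
            row <- categoryStats(paired, sets[[nm]], hq, label = nm)
            if (nm == "high_quality") row$wilcoxon_p <- NA_real_
            row
        })
        out <- do.call(rbind, rows)
        if (!is.null(tag)) out <- cbind(design_type = tag, out)
        out
    }
    if (!by_chemistry) return(build(flags, NULL))
    do.call(rbind, lapply(c("I", "II"), function(dt)
        build(flags[flags$design_type == dt, , drop = FALSE], dt)))
}

.isHighQuality <- function(flags) {
    !flags$multimap & !flags$repeat_overlap & !flags$indel_overlap &
        !flags$snp_at_cpg_c & !flags$snp_at_cpg_g &
        flags$body_snps_total == 0 &
        !(!is.na(flags$unknown_factor) & flags$unknown_factor)
}

#' 2-D beta-value density matrix
#'
#' Divides the unit square of (WGBS beta, array beta) pairs into
#' consecutive windows of size `window` (default 0.02, giving a 50 x 50
#' grid) and counts the pairs in each cell. The last bin on each axis is
#' closed so beta = 1 is countable; the total count is conserved.
#'
#' @param paired paired-beta data.frame from [pairProbeWgbs()].
#' @param window bin width on each axis.
#' @return an integer matrix with WGBS bins as rows and array bins as
#'   columns; dimnames give the left bin edges.
#' @export
densityMatrix <- function(paired, window = 0.02) {
    nb <- as.integer(ceiling(1 / window))
    bin <- function(b) pmin(as.integer(floor(b / window + 1e-9)), nb - 1L)
    m <- matrix(0L, nb, nb,
                dimnames = list(wgbs = format(window * seq_len(nb) - window),
                                array = format(window * seq_len(nb) - window)))
    if (nrow(paired)) {
        t2 <- table(factor(bin(paired$beta_wgbs), levels = 0:(nb - 1L)),
                    factor(bin(paired$beta_array), levels = 0:(nb - 1L)))
        m[] <- as.integer(t2)
    }
    m
}

#' Flag probes discordant with WGBS beyond an unexplained threshold
#'
#' A probe is flagged iff its absolute array-vs-WGBS beta difference is
#' strictly greater than the threshold (default 0.3); a difference of
#' exactly 0.3 is not flagged.
#'
#' @param paired paired-beta data.frame from [pairProbeWgbs()].
#' @param threshold strict cutoff on `abs_diff`.
#' @return character vector of flagged probe ids.
#' @export
flagUnknownFactors <- function(paired, threshold = 0.3) {
    paired$probe_id[paired$abs_diff > threshold]
}

#' Per-probe standard deviation over samples
#'
#' Sample standard deviation (n - 1 denominator) of each probe's betas
#' across samples. Probes with fewer than two non-missing values are
#' skipped and listed in the `"skipped"` attribute.
#'
#' @param mat probe-by-sample beta matrix.
#' @return named numeric vector of SDs.
#' @export
perProbeSd <- function(mat) {
    n_ok <- rowSums(!is.na(mat))
    keep <- n_ok >= 2L
    sds <- apply(mat[keep, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
    attr(sds, "skipped") <- rownames(mat)[!keep]
    sds
}

#' Compare per-probe SD distributions between kept and discarded probes
#'
#' Wilcoxon rank-sum test on the full SD distributions of the two groups,
#' with density summaries restricted to SDs at or above `min_sd` (default
#' 0.10) for reporting.
#'
#' @param sds named SD vector from [perProbeSd()].
#' @param keep_ids,discard_ids disjoint probe id sets.
#' @param min_sd reporting floor for the density summaries.
#' @return list with `p_value`, and `summary`: a data.frame per group of
#'   `n`, `n_reported` (SD >= `min_sd`), `median_sd`, `mean_sd` (the latter
#'   two over the reported subset).
#' @export
sdComparison <- function(sds, keep_ids, discard_ids, min_sd = 0.10) {
    keep <- sds[names(sds) %in% keep_ids]
    disc <- sds[names(sds) %in% discard_ids]
    if (!length(keep) || !length(disc))
        stop("both groups must be nonempty")
    p <- wilcoxonRankSum(keep, disc, mode = "normal")
    summ <- function(x, group) {
        r <- x[x >= min_sd]
        data.frame(group = group, n = length(x), n_reported = length(r),
                   median_sd = if (length(r)) stats::median(r) else NA_real_,
                   mean_sd = if (length(r)) mean(r) else NA_real_,
                   stringsAsFactors = FALSE)
    }
    list(p_value = p,
         summary = rbind(summ(keep, "keep"), summ(disc, "discard")))
}

#' Pooled beta histogram for a probe category
#'
#' Pools all sample betas of the category's probes into a histogram of 20
#' bins of width 0.05; the last bin is closed so beta = 1 is counted.
#'
#' @param mat probe-by-sample beta matrix.
#' @param ids probe ids forming the category.
#' @param bin_width histogram bin width.
#' @return data.frame `bin_start`, `bin_end`, `count`.
#' @export
categoryBetaDistribution <- function(mat, ids, bin_width = 0.05) {
    vals <- as.numeric(mat[rownames(mat) %in% ids, , drop = FALSE])
    vals <- vals[!is.na(vals)]
    nb <- as.integer(ceiling(1 / bin_width))
    idx <- pmin(as.integer(floor(vals / bin_width + 1e-9)), nb - 1L)
    counts <- tabulate(idx + 1L, nbins = nb)
    data.frame(bin_start = bin_width * (seq_len(nb) - 1L),
               bin_end = bin_width * seq_len(nb),
               count = counts)
}
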