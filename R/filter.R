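.REASONS <- c("MULTIMAP", "REPEAT", "INDEL", "SNP_AT_CPG",
              "BODY_SNP_TYPE_I", "BODY_SNP_TYPE_II", "UNKNOWN_FACTOR",
              "GENOTYPE")

#' Apply the probe-filtering decision workflow
#'
#' Evaluates every enabled factor for every probe and accumulates reason
#' codes in workflow order (multimapping, repeat, INDEL, SNP at CpG, body
#' SNP, unknown factor). A probe is discarded iff at least one enabled
#' reason fires; kept probes have an empty reason list. Reasons accumulate
#' rather than short-circuit because the accounting of probes affected by
#' multiple factors needs the full set.
#'
#' Rescue logic: bisulfite-okay body SNPs never count toward the body-SNP
#' reasons while `bisokay_rescue` is enabled; type II body SNPs fire only
#' when `drop_typeII_body_snp`. A probe carrying at least one factor flag
#' yet kept records how it survived in `rescued_by`: `BIS_OKAY` (all body
#' SNPs invisible in bisulfite space), `TYPE_II_TOLERANT` (type II chemistry
#' tolerates body SNPs), `INDEL_TOLERANT` (INDEL overlap kept by policy), or
#' `POLICY` (any other factor kept by configuration). Unevaluable flags
#' (`NA`, e.g. the unknown-factor flag without a WGBS pairing) never fire.
#'
#' @param flags `ProbeFlags` data.frame from [annotateProbes()].
#' @param config a [FilterConfig-class]; see [filterConfig()].
#' @return `FilterDecision` data.frame: `probe_id`, `verdict`
#'   (`"keep"`/`"discard"`), `reasons` (comma-joined codes, `""` when
#'   kept), `rescued_by` (`NA` or rescue class).
#' @export
applyFilter <- function(flags, config = filterConfig()) {
    need <- c("probe_id", "design_type", "multimap", "repeat_overlap",
              "indel_overlap", "snp_at_cpg_c", "snp_at_cpg_g",
              "body_snps_total", "body_snps_bisokay", "body_snps_effective",
              "unknown_factor")
    miss <- setdiff(need, colnames(flags))
    if (length(miss))
        stop("flags table is missing columns: ", paste(miss, collapse = ", "))
    nz <- function(x) !is.na(x) & x
    body_count <- if (config@bisokay_rescue) flags$body_snps_effective else
        flags$body_snps_total
    cpg <- nz(flags$snp_at_cpg_c) | nz(flags$snp_at_cpg_g)
    fire <- cbind(
        MULTIMAP = config@drop_multimap & nz(flags$multimap),
        REPEAT = config@drop_repeat & nz(flags$repeat_overlap),
        INDEL = config@drop_indel & nz(flags$indel_overlap),
        SNP_AT_CPG = config@drop_snp_at_cpg & cpg,
        BODY_SNP_TYPE_I = config@drop_typeI_body_snp &
            flags$design_type == "I" & nz(body_count > 0),
        BODY_SNP_TYPE_II = config@drop_typeII_body_snp &
            flags$design_type == "II" & nz(body_count > 0),
        UNKNOWN_FACTOR = nz(flags$unknown_factor))
    reasons <- apply(fire, 1L, function(r)
        paste(colnames(fire)[r], collapse = ","))
    verdict <- ifelse(reasons == "", "keep", "discard")

    any_factor <- .anyFactor(flags)
    rescued_by <- rep(NA_character_, nrow(flags))
    kept_flagged <- verdict == "keep" & any_factor
    all_bisokay <- flags$body_snps_total > 0 & flags$body_snps_effective == 0
    body_kept_ii <- flags$design_type == "II" & flags$body_snps_total > 0 &
        !config@drop_typeII_body_snp
    rescued_by[kept_flagged] <- "POLICY"
    rescued_by[kept_flagged & nz(flags$indel_overlap)] <- "INDEL_TOLERANT"
    rescued_by[kept_flagged & body_kept_ii] <- "TYPE_II_TOLERANT"
    rescued_by[kept_flagged & all_bisokay & config@bisokay_rescue] <-
        "BIS_OKAY"
    data.frame(probe_id = flags$probe_id, verdict = verdict,
               reasons = reasons, rescued_by = rescued_by,
               stringsAsFactors = FALSE)
}

# does the probe carry any genomic-factor flag (unknown included)?
.anyFactor <- function(flags) {
    nz <- function(x) !is.na(x) & x
    nz(flags$multimap) | nz(flags$repeat_overlap) |
        nz(flags$indel_overlap) | nz(flags$snp_at_cpg_c) |
        nz(flags$snp_at_cpg_g) | flags$body_snps_total > 0 |
        nz(flags$unknown_factor)
}

# per-probe count of distinct factors, for unique-category accounting
.factorMatrix <- function(flags) {
    nz <- function(x) !is.na(x) & x
    cbind(multimap = nz(flags$multimap),
          repeats = nz(flags$repeat_overlap),
          indel = nz(flags$indel_overlap),
          snp_at_cpg = nz(flags$snp_at_cpg_c) | nz(flags$snp_at_cpg_g),
          body_snp = flags$body_snps_total > 0,
          unknown = nz(flags$unknown_factor))
}

#' Override CpG-SNP decisions with sample genotypes
#'
#' When genotype calls for the profiled sample are available, probes whose
#' CpG-site SNP is homozygous reference at both dinucleotide positions are
#' rescued (the SNP is absent from this sample); homozygous alternate at
#' either position forces a discard with reason `GENOTYPE` (the interrogated
#' C is disrupted and the probe reads no methylation); heterozygous calls
#' leave the default verdict. Genotypes at positions not annotated with a
#' CpG-site SNP are ignored with a warning.
#'
#' @param decisions `FilterDecision` data.frame from [applyFilter()].
#' @param flags `ProbeFlags` data.frame.
#' @param probes the [ProbeSet-class] the flags were computed from.
#' @param genotypes data.frame `chrom`, `pos` (1-based), `zygosity`
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`; `"0/0"`, `"0/1"`, `"1/1"` also
#'   accepted).
#' @return adjusted `FilterDecision` data.frame.
#' @export
genotypeOverride <- function(decisions, flags, probes, genotypes) {
    pd <- probes@probeData
    zyg <- as.character(genotypes$zygosity)
    zyg[zyg %in% c("0/0", "0|0")] <- "hom_ref"
    zyg[zyg %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
    zyg[zyg %in% c("1/1", "1|1")] <- "hom_alt"
    gkey <- paste(genotypes$chrom, genotypes$pos)

    cpg_keys <- c(paste(pd$chrom, pd$cpg_pos)[flags$snp_at_cpg_c],
                  paste(pd$chrom, pd$cpg_pos + 1L)[flags$snp_at_cpg_g])
    orphan <- !gkey %in% cpg_keys
    if (any(orphan))
        warning(sum(orphan), " genotype calls at positions without an ",
                "annotated CpG-site SNP; ignored")

    z_at <- function(keys) zyg[match(keys, gkey)]
    for (i in seq_len(nrow(pd))) {
        if (!(flags$snp_at_cpg_c[i] || flags$snp_at_cpg_g[i])) next
        keys <- character(0)
        if (flags$snp_at_cpg_c[i])
            keys <- c(keys, paste(pd$chrom[i], pd$cpg_pos[i]))
        if (flags$snp_at_cpg_g[i])
            keys <- c(keys, paste(pd$chrom[i], pd$cpg_pos[i] + 1L))
        z <- z_at(keys)
        if (!length(z) || all(is.na(z))) next
        if (any(z == "hom_alt", na.rm = TRUE)) {
            reasons <- setdiff(strsplit(decisions$reasons[i], ",")[[1]],
                               "")
            decisions$reasons[i] <- paste(unique(c(reasons, "GENOTYPE")),
                                          collapse = ",")
            decisions$verdict[i] <- "discard"
            decisions$rescued_by[i] <- NA_character_
        } else if (all(z == "hom_ref", na.rm = TRUE) && !any(is.na(z))) {
            reasons <- setdiff(strsplit(decisions$reasons[i], ",")[[1]],
                               c("", "SNP_AT_CPG"))
            decisions$reasons[i] <- paste(reasons, collapse = ",")
            if (!length(reasons)) {
                decisions$verdict[i] <- "keep"
                decisions$rescued_by[i] <- "GENOTYPE"
            }
        }
    }
    decisions
}

#' Category counts with probes counted in every category they touch
#'
#' Each probe is counted in every category whose flag it carries (a probe
#' with both repeat and multimap flags appears in both rows), split by
#' Infinium chemistry. Also reports the high-quality and potentially noisy
#' totals; row totals equal the sum of the chemistry columns.
#'
#' @param flags `ProbeFlags` data.frame from [annotateProbes()].
#' @return data.frame `category`, `type_i`, `type_ii`, `total`.
#' @export
summarizeAnyOverlap <- function(flags) {
    nz <- function(x) !is.na(x) & x
    sets <- list(
        multimap = nz(flags$multimap),
        repeats = nz(flags$repeat_overlap),
        indel = nz(flags$indel_overlap),
        snp_at_cpg = nz(flags$snp_at_cpg_c) | nz(flags$snp_at_cpg_g),
        body_snp = flags$body_snps_total > 0,
        unknown = nz(flags$unknown_factor),
        high_quality = .isHighQuality(flags),
        noisy = .anyFactor(flags),
        total_probes = rep(TRUE, nrow(flags)))
    is_i <- flags$design_type == "I"
    rows <- lapply(names(sets), function(nm)
        data.frame(category = nm,
                   type_i = sum(sets[[nm]] & is_i),
                   type_ii = sum(sets[[nm]] & !is_i),
                   total = sum(sets[[nm]]), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Unique-category accounting of filtering decisions
#'
#' Probes carrying exactly one factor flag are counted under that factor
#' (the body-SNP factor split into single-SNP and two-or-more rows); probes
#' with two or more distinct factors fall under `multiple_factors`. Per-row
#' kept counts reflect rescues. Grand totals satisfy the partition
#' identities kept + discarded = total and kept = high_quality + rescued;
#' [verifyAccounting()] checks them and reports any violation.
#'
#' @param flags `ProbeFlags` data.frame.
#' @param decisions `FilterDecision` data.frame from [applyFilter()].
#' @return list with `categories` (data.frame `category`, `type_i`,
#'   `type_ii`, `kept`) and `totals` (data.frame `group`, `type_i`,
#'   `type_ii`, `total` for total/high_quality/rescued/kept/discarded).
#' @export
summarizeUnique <- function(flags, decisions) {
    stopifnot(identical(flags$probe_id, decisions$probe_id))
    fm <- .factorMatrix(flags)
    nfac <- rowSums(fm)
    kept <- decisions$verdict == "keep"
    is_i <- flags$design_type == "I"
    single <- function(col) nfac == 1L & fm[, col]
    cat_mask <- list(
        multimap = single("multimap"),
        repeats = single("repeats"),
        indel = single("indel"),
        snp_at_cpg = single("snp_at_cpg"),
        snp_body_1 = single("body_snp") & flags$body_snps_total == 1L,
        snp_body_2plus = single("body_snp") & flags$body_snps_total >= 2L,
        unknown = single("unknown"),
        multiple_factors = nfac >= 2L)
    categories <- do.call(rbind, lapply(names(cat_mask), function(nm) {
        m <- cat_mask[[nm]]
        data.frame(category = nm, type_i = sum(m & is_i),
                   type_ii = sum(m & !is_i), kept = sum(m & kept),
                   stringsAsFactors = FALSE)
    }))
    hq <- .isHighQuality(flags)
    rescued <- kept & nfac >= 1L
    tot <- function(mask, group)
        data.frame(group = group, type_i = sum(mask & is_i),
                   type_ii = sum(mask & !is_i), total = sum(mask),
                   stringsAsFactors = FALSE)
    totals <- rbind(tot(rep(TRUE, nrow(flags)), "total"),
                    tot(hq, "high_quality"),
                    tot(rescued, "rescued"),
                    tot(kept, "kept"),
                    tot(!kept, "discarded"))
    list(categories = categories, totals = totals)
}

#' Check the partition identities of an accounting summary
#'
#' @param summary output of [summarizeUnique()].
#' @return character vector of violated identities (empty when consistent).
#' @export
verifyAccounting <- function(summary) {
    t <- summary$totals
    g <- function(grp, col) t[t$group == grp, col]
    msgs <- character(0)
    for (col in c("type_i", "type_ii", "total")) {
        if (g("kept", col) + g("discarded", col) != g("total", col))
            msgs <- c(msgs, paste0("kept + discarded != total (", col, ")"))
        if (g("high_quality", col) + g("rescued", col) != g("kept", col))
            msgs <- c(msgs, paste0("high_quality + rescued != kept (",
                                   col, ")"))
    }
    if (sum(summary$categories$kept) !=
        g("rescued", "type_i") + g("rescued", "type_ii"))
        msgs <- c(msgs, "category kept column does not sum to rescued total")
    msgs
}

#' Rescued-probe counts by rescue class and chemistry
#'
#' Rescued probes carry at least one factor flag yet are kept; they are
#' partitioned by the `rescued_by` class assigned in [applyFilter()].
#' Totals are consistent with [summarizeUnique()]: rescued + high-quality
#' equals kept.
#'
#' @param flags `ProbeFlags` data.frame.
#' @param decisions `FilterDecision` data.frame.
#' @return data.frame `rescue_class`, `type_i`, `type_ii`, `total`, with a
#'   final `total` row.
#' @export
rescueReport <- function(flags, decisions) {
    stopifnot(identical(flags$probe_id, decisions$probe_id))
    rescued <- decisions$verdict == "keep" & .anyFactor(flags)
    is_i <- flags$design_type == "I"
    classes <- unique(stats::na.omit(decisions$rescued_by[rescued]))
    rows <- lapply(sort(classes), function(cl) {
        m <- rescued & !is.na(decisions$rescued_by) &
            decisions$rescued_by == cl
        data.frame(rescue_class = cl, type_i = sum(m & is_i),
                   type_ii = sum(m & !is_i), total = sum(m),
                   stringsAsFactors = FALSE)
    })
    rows <- c(rows, list(data.frame(
        rescue_class = "total", type_i = sum(rescued & is_i),
        type_ii = sum(rescued & !is_i), total = sum(rescued),
        stringsAsFactors = FALSE)))
    do.call(rbind, rows)
}

#' Fraction of probes removed per genomic region
#'
#' Assigns each probe to every region (by its interrogated CpG position)
#' and reports the removed/total fraction per region label. Regions with no
#' probes are reported as `NA`, not 0. Probes outside all regions are
#' unlabeled, so label-wise totals may sum to less than the probe count.
#'
#' @param probes a [ProbeSet-class].
#' @param decisions `FilterDecision` data.frame.
#' @param regions a `GRanges` with a `name` metadata column carrying the
#'   region label (island/shore/shelf/promoter/body or arbitrary), e.g.
#'   from `rtracklayer::import(..., format = "BED")`.
#' @return data.frame `region`, `n_probes`, `n_removed`, `fraction_removed`.
#' @export
regionRemovalFractions <- function(probes, decisions, regions) {
    pd <- probes@probeData
    labels <- if (!is.null(regions$name)) regions$name else
        as.character(seq_along(regions))
    cpg <- GenomicRanges::GRanges(pd$chrom,
                                  IRanges::IRanges(pd$cpg_pos, width = 1L))
    ov <- GenomicRanges::findOverlaps(cpg, regions, ignore.strand = TRUE)
    removed <- decisions$verdict[match(pd$probe_id, decisions$probe_id)] ==
        "discard"
    out <- lapply(unique(labels), function(lab) {
        ridx <- which(labels == lab)
        pidx <- unique(S4Vectors::queryHits(ov)[
            S4Vectors::subjectHits(ov) %in% ridx])
        n <- length(pidx)
        nr <- sum(removed[pidx])
        data.frame(region = lab, n_probes = n, n_removed = nr,
                   fraction_removed = if (n) nr / n else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Export and re-import the full filtering annotation
#'
#' One row per probe with every flag, count, the verdict, ordered reason
#' codes and the rescue class. The export round-trips losslessly through
#' [readAnnotations()] and is byte-deterministic for identical inputs.
#'
#' @param flags `ProbeFlags` data.frame.
#' @param decisions `FilterDecision` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportAnnotations <- function(flags, decisions, path) {
    stopifnot(identical(flags$probe_id, decisions$probe_id))
    out <- cbind(flags, decisions[, c("verdict", "reasons", "rescued_by")])
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
    invisible(path)
}

#' @rdname exportAnnotations
#' @return `readAnnotations()`: list with `flags` and `decisions`
#'   data.frames equal to the exported ones.
#' @export
readAnnotations <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$reasons[is.na(df$reasons)] <- ""
    dec_cols <- c("verdict", "reasons", "rescued_by")
    flags <- df[, setdiff(colnames(df), dec_cols), drop = FALSE]
    decisions <- data.frame(probe_id = df$probe_id, verdict = df$verdict,
                            reasons = df$reasons,
                            rescued_by = df$rescued_by,
                            stringsAsFactors = FALSE)
    list(flags = flags, decisions = decisions)
}
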