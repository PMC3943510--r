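#' Read a variant track (VCF subset or 6-column TSV)
#'
#' Accepts either a VCF (columns CHROM, POS, REF, ALT; optional INFO key
#' carrying average heterozygosity) or a tab-separated table with columns
#' `chrom`, `pos`, `ref`, `alt`, `vtype`, `avg_het`. Multi-allelic rows are
#' split into biallelic records before classification. Variant type is
#' derived from allele lengths: equal length 1 is a SNP, anything else an
#' INDEL.
#'
#' @param path file path; `.vcf` files go through VariantAnnotation.
#' @param het_info_key INFO key holding average heterozygosity (VCF input).
#' @return data.frame `chrom`, `pos` (1-based), `ref`, `alt`, `vtype`
#'   (`"SNP"`/`"INDEL"`), `avg_het` (fraction in \[0, 0.5\] or `NA`).
#' @export
readVariants <- function(path, het_info_key = "AVGHET") {
    if (!file.exists(path)) stop("variant file not found: ", path)
    if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
        vcf <- VariantAnnotation::readVcf(path)
        rr <- SummarizedExperiment::rowRanges(vcf)
        alt <- VariantAnnotation::alt(vcf)
        n_alt <- S4Vectors::elementNROWS(alt)
        idx <- rep(seq_along(rr), n_alt)
        het <- if (het_info_key %in%
                   rownames(VariantAnnotation::info(
                       VariantAnnotation::header(vcf))))
            as.numeric(VariantAnnotation::info(vcf)[[het_info_key]]) else
            rep(NA_real_, length(rr))
        df <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(rr))[idx],
            pos = BiocGenerics::start(rr)[idx],
            ref = as.character(VariantAnnotation::ref(vcf))[idx],
            alt = as.character(unlist(alt)),
            avg_het = het[idx], stringsAsFactors = FALSE)
    } else {
        df <- utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        need <- c("chrom", "pos", "ref", "alt")
        if (!all(need %in% colnames(df)))
            stop("variant TSV needs columns: ", paste(need, collapse = ", "))
        if (is.null(df$avg_het)) df$avg_het <- NA_real_
        # split multi-allelic rows (comma-separated ALT)
        alts <- strsplit(df$alt, ",", fixed = TRUE)
        idx <- rep(seq_len(nrow(df)), lengths(alts))
        df <- data.frame(chrom = df$chrom[idx], pos = as.integer(df$pos[idx]),
                         ref = toupper(df$ref[idx]),
                         alt = toupper(unlist(alts)),
                         avg_het = as.numeric(df$avg_het[idx]),
                         stringsAsFactors = FALSE)
    }
    df$vtype <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L,
                       "SNP", "INDEL")
    bad <- !is.na(df$avg_het) & (df$avg_het < 0 | df$avg_het > 0.5)
    if (any(bad)) {
        warning(sum(bad), " variants with avg_het outside [0, 0.5]; set NA")
        df$avg_het[bad] <- NA_real_
    }
    df
}

#' Read a repeat track (BED)
#'
#' @param path BED file (0-based half-open starts, as written by
#'   RepeatMasker-style exports); the name column is kept as repeat family.
#' @return a `GRanges` with a `family` metadata column.
#' @export
readRepeats <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    fam <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(family = fam)
    gr
}

#' Flag probes whose footprint overlaps a repeat element
#'
#' Half-open interval intersection with at least one shared base; abutting
#' intervals do not overlap. Probes on chromosomes absent from the repeat
#' track get `FALSE`.
#'
#' @param probes a [ProbeSet-class].
#' @param repeats a `GRanges` of repeat intervals (see [readRepeats()]).
#' @return named logical vector, one element per probe.
#' @export
overlapRepeats <- function(probes, repeats) {
    fp <- probeFootprints(probes)
    hit <- GenomicRanges::countOverlaps(fp, repeats,
                                        ignore.strand = TRUE) > 0L
    names(hit) <- names(fp)
    hit
}

#' Flag probes whose footprint overlaps an INDEL reference span
#'
#' An INDEL occupies the reference span `[pos, pos + nchar(ref))`. The flag
#' is annotation only; whether INDEL-overlapping probes are kept is the
#' filter engine's decision (they are kept under the default policy).
#'
#' @param probes a [ProbeSet-class].
#' @param variants variant data.frame from [readVariants()].
#' @return named logical vector, one element per probe.
#' @export
overlapIndels <- function(probes, variants) {
    fp <- probeFootprints(probes)
    ind <- variants[variants$vtype == "INDEL", , drop = FALSE]
    if (!nrow(ind)) {
        hit <- rep(FALSE, length(fp)); names(hit) <- names(fp); return(hit)
    }
    gr <- GenomicRanges::GRanges(ind$chrom, IRanges::IRanges(
        start = ind$pos, width = nchar(ind$ref)))
    hit <- GenomicRanges::countOverlaps(fp, gr, ignore.strand = TRUE) > 0L
    names(hit) <- names(fp)
    hit
}

#' Assign SNPs to probes with strand-oriented offsets
#'
#' Lists every SNP falling inside a probe's footprint or at the CpG
#' dinucleotide (forward positions `cpg_pos` and `cpg_pos + 1`, which for a
#' type II probe sit just outside the 50-bp footprint). The offset is the
#' signed distance from the interrogated C, oriented so that positive
#' offsets point into the probe body: `pos - cpg_pos` for plus-strand
#' probes and `cpg_pos - pos` for minus-strand probes.
#'
#' @param probes a [ProbeSet-class].
#' @param variants variant data.frame from [readVariants()].
#' @return data.frame with one row per (probe, SNP) assignment: `probe_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `avg_het`, `offset`, `at_cpg_c`,
#'   `at_cpg_g`, `in_footprint`.
#' @export
assignSnps <- function(probes, variants) {
    pd <- probes@probeData
    fp <- probeFootprints(probes)
    snp <- variants[variants$vtype == "SNP", , drop = FALSE]
    empty <- data.frame(probe_id = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), avg_het = numeric(0),
                        offset = integer(0), at_cpg_c = logical(0),
                        at_cpg_g = logical(0), in_footprint = logical(0),
                        stringsAsFactors = FALSE)
    if (!nrow(snp)) return(empty)
    snp_gr <- GenomicRanges::GRanges(snp$chrom,
                                     IRanges::IRanges(snp$pos, width = 1L))
    # search window: footprint extended to always include the CpG positions
    win <- GenomicRanges::GRanges(
        pd$chrom,
        IRanges::IRanges(
            start = pmin(BiocGenerics::start(fp), pd$cpg_pos),
            end = pmax(BiocGenerics::end(fp), pd$cpg_pos + 1L)))
    ov <- GenomicRanges::findOverlaps(win, snp_gr, ignore.strand = TRUE)
    if (!length(ov)) return(empty)
    pi <- S4Vectors::queryHits(ov)
    vi <- S4Vectors::subjectHits(ov)
    off <- ifelse(pd$strand[pi] == "+", snp$pos[vi] - pd$cpg_pos[pi],
                  pd$cpg_pos[pi] - snp$pos[vi])
    infp <- snp$pos[vi] >= BiocGenerics::start(fp)[pi] &
        snp$pos[vi] <= BiocGenerics::end(fp)[pi]
    data.frame(probe_id = pd$probe_id[pi], chrom = snp$chrom[vi],
               pos = snp$pos[vi], ref = snp$ref[vi], alt = snp$alt[vi],
               avg_het = snp$avg_het[vi], offset = as.integer(off),
               at_cpg_c = snp$pos[vi] == pd$cpg_pos[pi],
               at_cpg_g = snp$pos[vi] == pd$cpg_pos[pi] + 1L,
               in_footprint = infp, stringsAsFactors = FALSE)
}

#' Classify SNPs at the interrogated CpG dinucleotide
#'
#' `snp_at_cpg_c` is `TRUE` when a SNP sits at the forward-strand position
#' of the interrogated C, `snp_at_cpg_g` when at the paired G. An INDEL
#' whose reference span covers either dinucleotide position also sets the
#' corresponding flag (a disrupted CpG is a disrupted CpG regardless of
#' variant class).
#'
#' @param probes a [ProbeSet-class].
#' @param snps SNP assignments from [assignSnps()].
#' @param variants optional full variant data.frame; when provided, INDEL
#'   spans covering the CpG set the flags too.
#' @return data.frame `probe_id`, `snp_at_cpg_c`, `snp_at_cpg_g`.
#' @export
classifyCpgSnps <- function(probes, snps, variants = NULL) {
    pd <- probes@probeData
    at_c <- pd$probe_id %in% snps$probe_id[snps$at_cpg_c]
    at_g <- pd$probe_id %in% snps$probe_id[snps$at_cpg_g]
    if (!is.null(variants)) {
        ind <- variants[variants$vtype == "INDEL", , drop = FALSE]
        if (nrow(ind)) {
            igr <- GenomicRanges::GRanges(ind$chrom, IRanges::IRanges(
                start = ind$pos, width = nchar(ind$ref)))
            cgr <- GenomicRanges::GRanges(pd$chrom,
                                          IRanges::IRanges(pd$cpg_pos,
                                                           width = 1L))
            ggr <- GenomicRanges::GRanges(pd$chrom,
                                          IRanges::IRanges(pd$cpg_pos + 1L,
                                                           width = 1L))
            at_c <- at_c | GenomicRanges::countOverlaps(cgr, igr) > 0L
            at_g <- at_g | GenomicRanges::countOverlaps(ggr, igr) > 0L
        }
    }
    data.frame(probe_id = pd$probe_id, snp_at_cpg_c = at_c,
               snp_at_cpg_g = at_g, stringsAsFactors = FALSE)
}

#' Is a SNP invisible in bisulfite space?
#'
#' After bisulfite conversion, a C outside CpG context always reads as T, so
#' a C/T substitution whose immediate 3' neighbour (forward coordinates,
#' alleles normalised to the forward strand) is not a G cannot change the
#' converted sequence. Such SNPs are "bisulfite-okay" and their effects on
#' hybridization are ignored.
#'
#' @param variants variant data.frame rows (SNPs; INDELs return `FALSE`).
#' @param genome a named `DNAStringSet` (or FASTA path).
#' @return logical vector; `FALSE` with a warning when the downstream base
#'   is undefined (position at chromosome end or chromosome absent).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACATG"))
#' v <- data.frame(chrom = "chr1", pos = 2L, ref = "C", alt = "T",
#'                 vtype = "SNP", avg_het = NA)
#' isBisulfiteOkay(v, g)  # TRUE: C/T with downstream A
#' @export
isBisulfiteOkay <- function(variants, genome) {
    genome <- .asGenome(genome)
    n <- nrow(variants)
    ok <- logical(n)
    warned <- 0L
    for (i in seq_len(n)) {
        if (variants$vtype[i] != "SNP") next
        pair <- sort(c(variants$ref[i], variants$alt[i]))
        if (!identical(pair, c("C", "T"))) next
        chrom <- variants$chrom[i]
        pos <- variants$pos[i]
        if (!chrom %in% names(genome) ||
            pos + 1L > length(genome[[chrom]])) {
            warned <- warned + 1L
            next
        }
        nxt <- as.character(Biostrings::subseq(genome[[chrom]],
                                               pos + 1L, pos + 1L))
        ok[i] <- nxt != "G"
    }
    if (warned)
        warning(warned, " C/T SNPs with undefined downstream base; ",
                "treated as not bisulfite-okay")
    ok
}

#' Per-probe body-SNP counts with the bisulfite-space rescue
#'
#' Body SNPs are SNPs inside the footprint but not at the CpG dinucleotide.
#' `effective = total - bisokay`; a probe whose body SNPs are all
#' bisulfite-okay has an effective count of zero.
#'
#' @param probes a [ProbeSet-class].
#' @param snps SNP assignments from [assignSnps()].
#' @param genome reference genome for the downstream-base context.
#' @return data.frame `probe_id`, `body_snps_total`, `body_snps_bisokay`,
#'   `body_snps_effective`.
#' @export
effectiveBodySnpCounts <- function(probes, snps, genome) {
    pd <- probes@probeData
    body <- snps[snps$in_footprint & !snps$at_cpg_c & !snps$at_cpg_g, ,
                 drop = FALSE]
    total <- integer(nrow(pd)); bisok <- integer(nrow(pd))
    if (nrow(body)) {
        body$vtype <- "SNP"
        body$bisokay <- isBisulfiteOkay(body, genome)
        tt <- table(factor(body$probe_id, levels = pd$probe_id))
        bt <- table(factor(body$probe_id[body$bisokay],
                           levels = pd$probe_id))
        total <- as.integer(tt); bisok <- as.integer(bt)
    }
    data.frame(probe_id = pd$probe_id, body_snps_total = total,
               body_snps_bisokay = bisok,
               body_snps_effective = total - bisok,
               stringsAsFactors = FALSE)
}

#' Annotate every probe with all genomic-factor flags
#'
#' Orchestrates the per-factor operations into one flags table per probe:
#' multimapping, repeat overlap, INDEL overlap, SNPs at the CpG
#' dinucleotide, body-SNP counts (total / bisulfite-okay / effective),
#' maximum average heterozygosity over the probe's SNPs, and the
#' unknown-factor flag from the WGBS comparison. Flag computation is
#' order-independent: permuting probes or variants yields identical output
#' modulo row order (rows follow the input probe order).
#'
#' The unknown-factor flag requires a WGBS pairing (`paired`); when absent
#' or when a probe has no pair it is `NA` ("unevaluable") and never fires
#' in the filter engine.
#'
#' @param probes a [ProbeSet-class].
#' @param bsgenome a [BisulfiteGenome-class] (for multimapping).
#' @param repeats repeat `GRanges` (or `NULL` to skip; flags `FALSE`).
#' @param variants variant data.frame (or `NULL`; flags `FALSE`/0).
#' @param genome reference `DNAStringSet`/FASTA (bisulfite-okay contexts).
#' @param paired optional paired-beta data.frame from [pairProbeWgbs()].
#' @param unknown_threshold absolute beta-difference threshold (strict
#'   inequality) for the unknown-factor flag.
#' @param max_mismatch mismatches allowed in hit counting.
#' @return a `ProbeFlags` data.frame: `probe_id`, `design_type`, `multimap`,
#'   `repeat_overlap`, `indel_overlap`, `snp_at_cpg_c`, `snp_at_cpg_g`,
#'   `body_snps_total`, `body_snps_bisokay`, `body_snps_effective`,
#'   `max_avg_het`, `unknown_factor`.
#' @export
annotateProbes <- function(probes, bsgenome, repeats = NULL, variants = NULL,
                           genome = NULL, paired = NULL,
                           unknown_threshold = 0.3, max_mismatch = 0L) {
    pd <- probes@probeData
    mm <- flagMultimappers(probes, bsgenome, max_mismatch = max_mismatch)
    multimap <- pd$probe_id %in% mm$multimap
    rep_flag <- if (is.null(repeats))
        stats::setNames(rep(FALSE, nrow(pd)), pd$probe_id) else
        overlapRepeats(probes, repeats)
    if (is.null(variants))
        variants <- data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               vtype = character(0), avg_het = numeric(0),
                               stringsAsFactors = FALSE)
    indel_flag <- overlapIndels(probes, variants)
    snps <- assignSnps(probes, variants)
    cpg <- classifyCpgSnps(probes, snps, variants)
    body <- effectiveBodySnpCounts(probes, snps, genome)
    het <- rep(NA_real_, nrow(pd))
    if (nrow(snps)) {
        agg <- tapply(snps$avg_het, snps$probe_id,
                      function(x) if (all(is.na(x))) NA_real_ else
                          max(x, na.rm = TRUE))
        het <- as.numeric(agg[pd$probe_id])
    }
    unknown <- rep(NA, nrow(pd))
    if (!is.null(paired)) {
        uf <- flagUnknownFactors(paired, threshold = unknown_threshold)
        evaluable <- pd$probe_id %in% paired$probe_id
        unknown[evaluable] <- pd$probe_id[evaluable] %in% uf
    }
    data.frame(probe_id = pd$probe_id, design_type = pd$design_type,
               multimap = multimap,
               repeat_overlap = unname(rep_flag[pd$probe_id]),
               indel_overlap = unname(indel_flag[pd$probe_id]),
               snp_at_cpg_c = cpg$snp_at_cpg_c,
               snp_at_cpg_g = cpg$snp_at_cpg_g,
               body_snps_total = body$body_snps_total,
               body_snps_bisokay = body$body_snps_bisokay,
               body_snps_effective = body$body_snps_effective,
               max_avg_het = het, unknown_factor = unknown,
               stringsAsFactors = FALSE)
}

#' Stratify SNP-affected probes by maximum average heterozygosity
#'
#' Each SNP-affected probe (any CpG-site or body SNP) is assigned to the
#' stratum of its maximum average heterozygosity. Bins are left-closed,
#' right-open except the last, which is closed (so 0.5 lands in the top
#' stratum). Probes with unknown heterozygosity go to stratum `"unknown"`.
#' The strata partition the input.
#'
#' @param flags a `ProbeFlags` data.frame from [annotateProbes()].
#' @param bin_edges increasing numeric vector of stratum boundaries.
#' @return data.frame `probe_id`, `max_avg_het`, `stratum` (character).
#' @export
heterozygosityStrata <- function(flags,
                                 bin_edges = c(0, 0.1, 0.2, 0.3, 0.4, 0.5)) {
    if (is.unsorted(bin_edges, strictly = TRUE))
        stop("bin_edges must be strictly increasing")
    affected <- flags$body_snps_total > 0 | flags$snp_at_cpg_c |
        flags$snp_at_cpg_g
    sub <- flags[affected, c("probe_id", "max_avg_het"), drop = FALSE]
    k <- length(bin_edges)
    labels <- paste0("[", bin_edges[-k], ",", bin_edges[-1],
                     c(rep(")", k - 2), "]"))
    stratum <- as.character(cut(sub$max_avg_het, breaks = bin_edges,
                                labels = labels, right = FALSE,
                                include.lowest = TRUE))
    # right = FALSE + include.lowest puts the maximum edge in the last bin
    stratum[is.na(stratum)] <- "unknown"
    data.frame(probe_id = sub$probe_id, max_avg_het = sub$max_avg_het,
               stratum = stratum, stringsAsFactors = FALSE)
}

#' Beta-difference profile by body-SNP offset
#'
#' For each probe carrying body SNPs, takes the offset of its nearest body
#' SNP (smallest strand-oriented distance from the interrogated C) and
#' summarises the absolute array-vs-WGBS beta difference per offset bin.
#' Used to check for positional bias of SNP effects along the probe body.
#'
#' @param snps SNP assignments from [assignSnps()].
#' @param paired paired-beta data.frame from [pairProbeWgbs()].
#' @return data.frame `offset`, `n`, `median_abs_diff`, one row per offset
#'   observed; empty when no SNP-bearing probe has a pairing.
#' @export
snpOffsetProfile <- function(snps, paired) {
    body <- snps[snps$in_footprint & !snps$at_cpg_c & !snps$at_cpg_g, ,
                 drop = FALSE]
    if (!nrow(body) || !nrow(paired))
        return(data.frame(offset = integer(0), n = integer(0),
                          median_abs_diff = numeric(0)))
    nearest <- tapply(abs(body$offset), body$probe_id, min)
    df <- data.frame(probe_id = names(nearest),
                     offset = as.integer(nearest),
                     stringsAsFactors = FALSE)
    df <- merge(df, paired[, c("probe_id", "abs_diff")], by = "probe_id")
    if (!nrow(df))
        return(data.frame(offset = integer(0), n = integer(0),
                          median_abs_diff = numeric(0)))
    agg <- aggregate(abs_diff ~ offset, data = df,
                     FUN = function(x) c(n = length(x),
                                         med = stats::median(x)))
    out <- data.frame(offset = agg$offset,
                      n = as.integer(agg$abs_diff[, "n"]),
                      median_abs_diff = agg$abs_diff[, "med"])
    out[order(out$offset), , drop = FALSE]
}
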