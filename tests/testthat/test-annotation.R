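mkProbe <- function(id = "p1", dt = "I", chrom = "chr1", pos = 1001L,
                    strand = "+") {
    data.frame(probe_id = id, design_type = dt, chrom = chrom,
               cpg_pos = pos, strand = strand,
               probe_seq = strrep("ACGTA", 10), stringsAsFactors = FALSE)
}

test_that("repeat overlap uses half-open intersection and matches the all-pairs oracle", {
    ps <- ProbeSet(mkProbe())  # footprint [1000, 1050) in 0-based terms
    mk_rep <- function(s0, e0) GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(s0 + 1L, e0))
    expect_true(unname(overlapRepeats(ps, mk_rep(1049L, 1100L))))
    expect_false(unname(overlapRepeats(ps, mk_rep(1050L, 1100L))))
    expect_false(unname(suppressWarnings(overlapRepeats(
        ps, GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 5000))))))

    set.seed(202)
    n <- 1000L
    probes <- ProbeSet(data.frame(
        probe_id = sprintf("p%04d", seq_len(n)),
        design_type = sample(c("I", "II"), n, TRUE),
        chrom = sample(c("chr1", "chr2"), n, TRUE),
        cpg_pos = sample(200:49800, n),
        strand = sample(c("+", "-"), n, TRUE),
        probe_seq = strrep("ACGTA", 10), stringsAsFactors = FALSE))
    m <- 200L
    rs <- sample(0:49950, m); re <- rs + sample(10:400, m, TRUE)
    rchr <- sample(c("chr1", "chr2"), m, TRUE)
    reps <- GenomicRanges::GRanges(rchr, IRanges::IRanges(rs + 1L, re))
    got <- unname(overlapRepeats(probes, reps))
    fp <- probeFootprints(probes)
    want <- oracleOverlap(BiocGenerics::start(fp) - 1L,
                          BiocGenerics::end(fp),
                          as.character(GenomicRanges::seqnames(fp)),
                          rs, re, rchr)
    expect_identical(got, want)
})

test_that("INDEL overlap follows the reference span and fixture plantings", {
    ps <- ProbeSet(mkProbe())  # footprint 1001..1050 (1-based)
    del_in <- data.frame(chrom = "chr1", pos = 1020L, ref = "TTT",
                         alt = "T", vtype = "INDEL", avg_het = NA)
    expect_true(unname(overlapIndels(ps, del_in)))
    ins_out <- data.frame(chrom = "chr1", pos = 1051L, ref = "A",
                          alt = "ATG", vtype = "INDEL", avg_het = NA)
    expect_false(unname(overlapIndels(ps, ins_out)))
    # but a deletion whose span reaches back into the footprint overlaps
    del_edge <- data.frame(chrom = "chr1", pos = 1050L, ref = "AAA",
                           alt = "A", vtype = "INDEL", avg_het = NA)
    expect_true(unname(overlapIndels(ps, del_edge)))

    ann <- sharedAnnotation()
    expect_equal(sum(ann$flags$indel_overlap),
                 sum(ann$fx$truth$indel_overlap))
    expect_setequal(ann$flags$probe_id[ann$flags$indel_overlap],
                    ann$fx$truth$probe_id[ann$fx$truth$indel_overlap])
})

test_that("SNP assignment reports strand-oriented offsets from the interrogated C", {
    snp <- function(pos) data.frame(chrom = "chr1", pos = pos, ref = "A",
                                    alt = "G", vtype = "SNP", avg_het = 0.2)
    ps_plus <- ProbeSet(mkProbe(strand = "+"))
    a <- assignSnps(ps_plus, snp(1001L))
    expect_equal(a$offset, 0L)
    expect_true(a$at_cpg_c)
    # 10 bases into the body of a minus-strand probe: forward pos - 10
    ps_minus <- ProbeSet(mkProbe(strand = "-"))
    a <- assignSnps(ps_minus, snp(991L))
    expect_equal(a$offset, 10L)
    expect_false(a$at_cpg_c || a$at_cpg_g)
    # no SNPs in reach
    expect_equal(nrow(assignSnps(ps_plus, snp(5000L))), 0L)
    # the CpG G of a type II plus probe sits inside its footprint
    ps2 <- ProbeSet(mkProbe(dt = "II"))
    a <- assignSnps(ps2, snp(1002L))
    expect_true(a$at_cpg_g)
    # and the C, though outside the footprint, is still assigned
    a <- assignSnps(ps2, snp(1001L))
    expect_true(a$at_cpg_c)
    expect_false(a$in_footprint)
})

test_that("CpG-site classification covers SNPs and CpG-spanning INDELs", {
    ps <- ProbeSet(mkProbe())
    snp_at <- function(pos) data.frame(chrom = "chr1", pos = pos,
                                       ref = "C", alt = "A", vtype = "SNP",
                                       avg_het = NA)
    cls <- function(v) classifyCpgSnps(ps, assignSnps(ps, v), v)
    expect_equal(unlist(cls(snp_at(1001L))[, 2:3]),
                 c(snp_at_cpg_c = TRUE, snp_at_cpg_g = FALSE))
    expect_equal(unlist(cls(snp_at(1002L))[, 2:3]),
                 c(snp_at_cpg_c = FALSE, snp_at_cpg_g = TRUE))
    both <- rbind(snp_at(1001L), snp_at(1002L))
    expect_equal(unlist(cls(both)[, 2:3]),
                 c(snp_at_cpg_c = TRUE, snp_at_cpg_g = TRUE))
    del <- data.frame(chrom = "chr1", pos = 1000L, ref = "AAAA", alt = "A",
                      vtype = "INDEL", avg_het = NA)
    got <- cls(del)
    expect_true(got$snp_at_cpg_c && got$snp_at_cpg_g)
})

test_that("bisulfite-okay classification matches exhaustive enumeration of all 48 cases", {
    bases <- c("A", "C", "G", "T")
    cases <- expand.grid(ref = bases, alt = bases, nxt = bases,
                         stringsAsFactors = FALSE)
    cases <- cases[cases$ref != cases$alt, ]
    expect_equal(nrow(cases), 48L)
    for (i in seq_len(nrow(cases))) {
        g <- Biostrings::DNAStringSet(stats::setNames(
            paste0("AA", cases$ref[i], cases$nxt[i], "AA"), "chr1"))
        v <- data.frame(chrom = "chr1", pos = 3L, ref = cases$ref[i],
                        alt = cases$alt[i], vtype = "SNP", avg_het = NA)
        want <- setequal(c(cases$ref[i], cases$alt[i]), c("C", "T")) &&
            cases$nxt[i] != "G"
        expect_identical(isBisulfiteOkay(v, g), want,
                         label = paste(cases$ref[i], cases$alt[i],
                                       cases$nxt[i]))
    }
    # undefined downstream base: not okay, with a warning
    g <- Biostrings::DNAStringSet(c(chr1 = "AAC"))
    v <- data.frame(chrom = "chr1", pos = 3L, ref = "C", alt = "T",
                    vtype = "SNP", avg_het = NA)
    expect_warning(ok <- isBisulfiteOkay(v, g), "downstream")
    expect_false(ok)
})

test_that("effective body-SNP counts subtract bisulfite-okay SNPs", {
    g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 1100)))
    ps <- ProbeSet(mkProbe())  # footprint 1001..1050, plus strand
    two_ok <- data.frame(chrom = "chr1", pos = c(1010L, 1020L), ref = "C",
                         alt = "T", vtype = "SNP", avg_het = NA)
    got <- effectiveBodySnpCounts(ps, assignSnps(ps, two_ok), g)
    expect_equal(unlist(got[, 2:4]),
                 c(body_snps_total = 2L, body_snps_bisokay = 2L,
                   body_snps_effective = 0L))
    one_bad <- data.frame(chrom = "chr1", pos = 1010L, ref = "G",
                          alt = "A", vtype = "SNP", avg_het = NA)
    got <- effectiveBodySnpCounts(ps, assignSnps(ps, one_bad), g)
    expect_equal(unlist(got[, 2:4]),
                 c(body_snps_total = 1L, body_snps_bisokay = 0L,
                   body_snps_effective = 1L))

    ann <- sharedAnnotation()
    expect_equal(ann$flags$body_snps_total, ann$fx$truth$body_snps_total)
    expect_equal(ann$flags$body_snps_bisokay,
                 ann$fx$truth$body_snps_bisokay)
})

test_that("heterozygosity strata partition SNP-affected probes", {
    flags <- rbind(flagsRow("a", body_snps_total = 1L, max_avg_het = 0.25),
                   flagsRow("b", body_snps_total = 1L, max_avg_het = 0.5),
                   flagsRow("c", snp_at_cpg_c = TRUE,
                            max_avg_het = NA_real_),
                   flagsRow("d"),  # unaffected, excluded
                   flagsRow("e", body_snps_total = 2L, max_avg_het = 0.0))
    st <- heterozygosityStrata(flags)
    expect_equal(nrow(st), 4L)  # d is not SNP-affected
    expect_equal(st$stratum[st$probe_id == "a"], "[0.2,0.3)")
    expect_equal(st$stratum[st$probe_id == "b"], "[0.4,0.5]")
    expect_equal(st$stratum[st$probe_id == "c"], "unknown")
    expect_equal(st$stratum[st$probe_id == "e"], "[0,0.1)")
    expect_error(heterozygosityStrata(flags, bin_edges = c(0.3, 0.1)),
                 "increasing")
})

test_that("SNP-offset profile summarises nearest body SNPs", {
    snps <- data.frame(probe_id = "p1", chrom = "chr1", pos = 1008L,
                       ref = "A", alt = "G", avg_het = 0.2, offset = 7L,
                       at_cpg_c = FALSE, at_cpg_g = FALSE,
                       in_footprint = TRUE, stringsAsFactors = FALSE)
    paired <- data.frame(probe_id = "p1", beta_array = 0.5,
                         beta_wgbs = 0.4, abs_diff = 0.1,
                         signed_diff = 0.1, stringsAsFactors = FALSE)
    prof <- snpOffsetProfile(snps, paired)
    expect_equal(prof$offset, 7L)
    expect_equal(prof$n, 1L)
    expect_equal(prof$median_abs_diff, 0.1)
    # no SNP-bearing probes: empty profile
    expect_equal(nrow(snpOffsetProfile(snps[0, ], paired)), 0L)

    # offset-independent noise: medians stay within Monte-Carlo spread
    set.seed(99)
    n <- 3000L
    offs <- sample(2:48, n, TRUE)
    snps2 <- data.frame(probe_id = sprintf("s%05d", seq_len(n)),
                        chrom = "chr1", pos = 1000L + offs, ref = "A",
                        alt = "G", avg_het = NA_real_, offset = offs,
                        at_cpg_c = FALSE, at_cpg_g = FALSE,
                        in_footprint = TRUE, stringsAsFactors = FALSE)
    d <- abs(rnorm(n, 0, 0.05))
    paired2 <- data.frame(probe_id = snps2$probe_id, beta_array = 0.5 + d,
                          beta_wgbs = 0.5, abs_diff = d, signed_diff = d,
                          stringsAsFactors = FALSE)
    prof2 <- snpOffsetProfile(snps2, paired2)
    expect_true(max(prof2$median_abs_diff) - min(prof2$median_abs_diff) <
                0.05)
})

test_that("variant reading handles VCF with INFO heterozygosity and multi-allelic splitting", {
    dir <- sharedFixtureDir()
    v <- readVariants(file.path(dir, "variants.vcf"))
    fx <- sharedFixture()
    expect_equal(nrow(v), nrow(fx$variants))
    expect_setequal(v$vtype, unique(fx$variants$vtype))
    key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
    expect_setequal(key(v), key(fx$variants))
    m <- match(key(fx$variants), key(v))
    expect_equal(round(v$avg_het[m], 4), round(fx$variants$avg_het, 4))

    # TSV route with a multi-allelic row
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("chrom\tpos\tref\talt\tvtype\tavg_het",
                 "chr1\t100\tA\tG,T\tSNP\t0.2",
                 "chr1\t200\tAT\tA\tINDEL\tNA"), tsv)
    vt <- readVariants(tsv)
    expect_equal(nrow(vt), 3L)
    expect_equal(vt$vtype, c("SNP", "SNP", "INDEL"))
})

test_that("probe flags are invariant to probe and variant permutations", {
    ann <- sharedAnnotation()
    fx <- ann$fx
    set.seed(13)
    perm_p <- sample(length(fx$probes))
    perm_v <- sample(nrow(fx$variants))
    flags2 <- annotateProbes(fx$probes[perm_p], ann$bsg, fx$repeats,
                             fx$variants[perm_v, ], fx$genome,
                             paired = ann$paired)
    reord <- flags2[match(ann$flags$probe_id, flags2$probe_id), ]
    rownames(reord) <- NULL
    expect_equal(reord, ann$flags)
})
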