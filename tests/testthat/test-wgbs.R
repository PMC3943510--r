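writeWgbs <- function(lines) {
    f <- tempfile(fileext = ".bedgraph")
    writeLines(lines, f)
    f
}

test_that("WGBS loading applies the 5-read coverage floor and score scaling", {
    f <- writeWgbs(c("chr1\t99\t100\t80\t4",
                     "chr1\t199\t200\t100\t5",
                     "chr1\t299\t300\t0\t30"))
    s <- readWgbsSites(f)
    expect_equal(nrow(s), 2L)
    expect_equal(attr(s, "n_low_coverage"), 1L)
    expect_equal(s$pos, c(200L, 300L))
    expect_equal(s$beta, c(1.0, 0.0))
    # 4-column dialect (1-based positions)
    f4 <- writeWgbs("chr1\t200\t50\t10")
    s4 <- readWgbsSites(f4)
    expect_equal(s4$pos, 200L)
    expect_equal(s4$beta, 0.5)
    # empty file and out-of-range scores
    expect_equal(nrow(readWgbsSites(writeWgbs(character(0)))), 0L)
    expect_warning(s5 <- readWgbsSites(writeWgbs("chr1\t99\t100\t140\t9")),
                   "score")
    expect_equal(nrow(s5), 0L)
})

test_that("probe/WGBS pairing matches positions exactly and computes differences", {
    ps <- ProbeSet(data.frame(
        probe_id = c("pA", "pB"), design_type = "I", chrom = "chr1",
        cpg_pos = c(1001L, 2001L), strand = "+",
        probe_seq = strrep("ACGTA", 10), stringsAsFactors = FALSE))
    sites <- data.frame(chrom = "chr1", pos = 1001L, beta = 0.5,
                        coverage = 10L, stringsAsFactors = FALSE)
    paired <- pairProbeWgbs(ps, sites, c(pA = 0.9, pB = 0.4))
    expect_equal(paired$probe_id, "pA")
    expect_equal(paired$abs_diff, 0.4)
    expect_equal(paired$signed_diff, 0.4)
    expect_equal(attr(paired, "unmatched"), "pB")
    # duplicate site rows: higher coverage wins, with a warning
    dup <- rbind(sites, data.frame(chrom = "chr1", pos = 1001L,
                                   beta = 0.9, coverage = 30L))
    expect_warning(p2 <- pairProbeWgbs(ps, dup, c(pA = 0.9)), "coverage")
    expect_equal(p2$beta_wgbs, 0.9)

    # fixture: matched pairs equal the planted covered probes
    ann <- sharedAnnotation()
    expect_equal(sort(ann$paired$probe_id),
                 sort(ann$fx$truth$probe_id[ann$fx$truth$wgbs_covered]))
})

test_that("rank-sum test: exact enumeration, identical samples, and normal approximation", {
    expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6)), 0.1)
    expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6)),
                 oracleWilcoxP(c(1, 2, 3), c(4, 5, 6)))
    x <- c(0.1, 0.2, 0.3, 0.4)
    expect_gte(wilcoxonRankSum(x, x), 0.99)
    set.seed(5)
    for (k in 1:25) {
        v <- sample(10000L, 16)
        a <- v[1:8]; b <- v[9:16]
        expect_equal(wilcoxonRankSum(a, b, mode = "exact"),
                     oracleWilcoxP(a, b))
    }
    # exhaustive n=8/8 comparison of the normal route against the exact
    # route over every achievable U statistic: agreement within 10%
    # wherever the exact p is at least 0.05, and small absolute deviation
    # throughout the tail (the normal approximation is relatively loose in
    # the extreme tail by its nature)
    for (U in 0:64) {
        S <- 1:8; rem <- U; i <- 8L
        while (rem > 0L) {
            d <- min(rem, 8L); S[i] <- S[i] + d; rem <- rem - d
            i <- i - 1L
        }
        a <- S; b <- setdiff(1:16, S)
        pe <- wilcoxonRankSum(a, b, mode = "exact")
        pn <- wilcoxonRankSum(a, b, mode = "normal")
        if (pe >= 0.05) expect_lt(abs(pn - pe) / pe, 0.10)
        expect_lt(abs(pn - pe), 0.012)
    }
    expect_error(wilcoxonRankSum(c(1, 1, 2), c(1, 3, 4), mode = "exact"),
                 "ties")
    expect_error(wilcoxonRankSum(numeric(0), 1), "nonempty")
})

test_that("category statistics reproduce the defining examples", {
    mk_paired <- function(id, d) data.frame(
        probe_id = id, beta_array = 0.5 + d, beta_wgbs = 0.5,
        abs_diff = abs(d), signed_diff = d, stringsAsFactors = FALSE)
    paired <- mk_paired(c("a", "b", "c"), c(0.1, 0.2, 0.3))
    st <- categoryStats(paired, c("a", "b", "c"), c("a", "b", "c"))
    expect_equal(st$median_abs_diff, 0.2)
    expect_gte(st$wilcoxon_p, 0.99)

    # Pearson endpoints and a direct-formula spot check
    x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 5)
    id <- letters[1:4]
    p_id <- data.frame(probe_id = id, beta_array = x, beta_wgbs = x,
                       abs_diff = 0, signed_diff = 0)
    expect_equal(categoryStats(p_id, id, id)$pearson_r, 1.0)
    p_anti <- data.frame(probe_id = id, beta_array = -x, beta_wgbs = x,
                         abs_diff = abs(2 * x), signed_diff = -2 * x)
    expect_equal(categoryStats(p_anti, id, id)$pearson_r, -1.0)
    p_xy <- data.frame(probe_id = id, beta_array = y, beta_wgbs = x,
                       abs_diff = abs(y - x), signed_diff = y - x)
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(categoryStats(p_xy, id, id)$pearson_r, r_direct)

    # inflated-noise category is detected
    set.seed(21)
    bg <- mk_paired(sprintf("bg%03d", 1:500), rnorm(500, 0, 0.05))
    noisy <- mk_paired(sprintf("nz%03d", 1:500), rnorm(500, 0, 0.15))
    st2 <- categoryStats(rbind(bg, noisy), noisy$probe_id, bg$probe_id)
    expect_lt(st2$wilcoxon_p, 0.001)
    expect_gt(st2$median_abs_diff,
              categoryStats(rbind(bg, noisy), bg$probe_id,
                            bg$probe_id)$median_abs_diff)

    # empty category
    st3 <- categoryStats(paired, character(0), c("a", "b"))
    expect_equal(st3$n, 0L)
    expect_true(is.na(st3$median_abs_diff))
})

test_that("density matrix bins at 0.02 with a closed last bin and conserved counts", {
    mk <- function(w, a) data.frame(probe_id = seq_along(w),
                                    beta_array = a, beta_wgbs = w,
                                    abs_diff = abs(a - w),
                                    signed_diff = a - w)
    m <- densityMatrix(mk(0, 0))
    expect_equal(dim(m), c(50L, 50L))
    expect_equal(m[1, 1], 1L)
    m <- densityMatrix(mk(1, 1))
    expect_equal(m[50, 50], 1L)
    m <- densityMatrix(mk(0.02, 0.019999))
    expect_equal(m[2, 1], 1L)
    set.seed(8)
    pr <- mk(runif(500), runif(500))
    expect_equal(sum(densityMatrix(pr)), 500L)
})

test_that("unknown-factor threshold is strict at 0.3", {
    paired <- data.frame(probe_id = c("x", "y", "z"),
                         beta_array = c(0.3, 0.31, 0.1),
                         beta_wgbs = c(0, 0, 0),
                         abs_diff = c(0.3, 0.31, 0.1),
                         signed_diff = c(0.3, 0.31, 0.1))
    expect_equal(flagUnknownFactors(paired), "y")
    expect_length(flagUnknownFactors(paired[paired$abs_diff < 0.2, ]), 0L)
})

test_that("per-probe SD uses the n-1 denominator and skips single-value rows", {
    m <- rbind(const = c(0.5, 0.5, 0.5, 0.5),
               pair = c(0, 1, NA, NA),
               single = c(0.3, NA, NA, NA))
    sds <- perProbeSd(m)
    expect_equal(unname(sds["const"]), 0)
    expect_equal(unname(sds["pair"]), sqrt(0.5))
    expect_equal(attr(sds, "skipped"), "single")
})

test_that("SD comparison separates noisy from quiet probes and filters reporting", {
    set.seed(31)
    n <- 300L; ns <- 10L
    true <- runif(2 * n)
    noise_sd <- rep(c(0.05, 0.15), each = n)
    m <- pmin(pmax(true + matrix(rnorm(2 * n * ns), ncol = ns) * noise_sd,
                   0), 1)
    rownames(m) <- c(sprintf("k%04d", 1:n), sprintf("d%04d", 1:n))
    sds <- perProbeSd(m)
    res <- sdComparison(sds, rownames(m)[1:n], rownames(m)[(n + 1):(2 * n)])
    expect_lt(res$p_value, 1e-4)
    expect_lt(median(sds[1:n]), median(sds[(n + 1):(2 * n)]))
    # the reporting floor removes exactly the sub-threshold probes
    expect_equal(res$summary$n_reported[1], sum(sds[1:n] >= 0.10))
    expect_error(sdComparison(sds, character(0), rownames(m)), "nonempty")
})

test_that("category beta histograms conserve mass and find the modal bin", {
    m <- matrix(0.975, nrow = 3, ncol = 4,
                dimnames = list(c("a", "b", "c"), NULL))
    h <- categoryBetaDistribution(m, c("a", "b"))
    expect_equal(sum(h$count), 8L)
    expect_equal(h$count[20], 8L)
    m[1, 1] <- NA
    h2 <- categoryBetaDistribution(m, c("a", "b"))
    expect_equal(sum(h2$count), 7L)
})

test_that("signed differences recover an injected array bias", {
    # symmetric noise, betas away from the clamping boundaries
    set.seed(17)
    n <- 4000L
    true <- runif(n, 0.2, 0.7)
    wgbs <- rbinom(n, 30, true) / 30
    arr0 <- true + rnorm(n, 0, 0.05)
    mk <- function(arr) data.frame(probe_id = seq_len(n),
                                   beta_array = arr, beta_wgbs = wgbs,
                                   abs_diff = abs(arr - wgbs),
                                   signed_diff = arr - wgbs)
    expect_lt(abs(mean(mk(arr0)$signed_diff)), 0.01)
    shift <- mean(mk(arr0 + 0.05)$signed_diff) -
        mean(mk(arr0)$signed_diff)
    expect_lt(abs(shift - 0.05), 0.005)
})
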