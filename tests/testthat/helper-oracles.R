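# Independent oracles used to cross-check package computations. These share
# no code with the implementation paths they verify.

# reverse complement of a plain character string
revcompStr <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
}

# brute-force sliding-window hit count of a wildcard query over both
# converted strand texts of a genome, via the regex engine with an
# overlap-tolerant lookahead
oracleHitCount <- function(query, genome_strings) {
    pat <- gsub("R", "[AG]", gsub("Y", "[CT]", query))
    pat <- paste0("(?=", pat, ")")
    tot <- 0L
    for (s in genome_strings) {
        for (txt in c(chartr("C", "T", s),
                      chartr("C", "T", revcompStr(s)))) {
            m <- gregexpr(pat, txt, perl = TRUE)[[1]]
            tot <- tot + sum(m > 0L)
        }
    }
    tot
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (no ties, small n only)
oracleWilcoxP <- function(a, b) {
    na <- length(a); nb <- length(b); n <- na + nb
    stopifnot(!any(duplicated(c(a, b))))
    r <- rank(c(a, b))
    u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    combs <- utils::combn(n, na)
    u_all <- colSums(matrix(seq_len(n)[combs], nrow = na)) -
        na * (na + 1) / 2
    min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# quadratic all-pairs interval overlap (0-based half-open)
oracleOverlap <- function(fp_start0, fp_end0, fp_chrom,
                          rep_start0, rep_end0, rep_chrom) {
    vapply(seq_along(fp_start0), function(i) {
        any(rep_chrom == fp_chrom[i] &
                rep_start0 < fp_end0[i] & rep_end0 > fp_start0[i])
    }, logical(1))
}

# random DNA string
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
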