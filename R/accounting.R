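#' Published category counts for the full HM450K array
#'
#' The per-chemistry probe counts established for the complete 485,512-probe
#' HM450K manifest by the published WGBS-based probe-quality assessment this
#' package's workflow implements. These are transcription-level inputs, not
#' results computed here: the pipeline can regenerate a full annotation
#' given real genome, dbSNP, RepeatMasker and WGBS resources, but those are
#' not shipped. The counts feed [arrayAccounting()] to reproduce the
#' published filtering arithmetic (kept/discarded totals and removal
#' fractions).
#'
#' `any_overlap` counts probes in every category they touch;
#' `unique_category` counts each affected probe once, under its single
#' factor or under `multiple_factors`, with the kept column reflecting
#' rescues. A printed-source quirk is retained deliberately: the published
#' unknown-factors any-overlap row totals 15,440 while its chemistry split
#' (1,394 + 13,840) sums to 15,234; [arrayAccounting()] reports computed
#' sums and surfaces such inconsistencies rather than forcing agreement.
#'
#' @return list with `totals`, `high_quality`, `rescued` (each a vector
#'   `c(I = , II = )`), `any_overlap` and `unique_category` data.frames.
#' @export
hm450kReferenceCounts <- function() {
    list(
        totals = c(I = 135476, II = 350036),
        high_quality = c(I = 52817, II = 119770),
        rescued = c(I = 7367, II = 114886),
        any_overlap = data.frame(
            category = c("multimap", "indel_only", "repeats", "snp_at_cpg",
                         "snp_body", "unknown"),
            type_i = c(5971, 1935, 8438, 12746, 52175, 1394),
            type_ii = c(13863, 4348, 30305, 57372, 117342, 13840),
            printed_total = c(19834, 6283, 38743, 70118, 169517, 15440),
            stringsAsFactors = FALSE),
        unique_category = data.frame(
            category = c("multimap", "repeats", "indel", "snp_at_cpg",
                         "snp_body_1", "snp_body_2plus", "unknown",
                         "multiple_factors"),
            type_i = c(1581, 2845, 1885, 9568, 26700, 20043, 1394, 16857),
            type_ii = c(3728, 13673, 4101, 42800, 72315, 34330, 13840,
                        49580),
            kept = c(0, 0, 5986, 0, 77545, 34675, 0, 4047),
            stringsAsFactors = FALSE))
}

#' Filtering accountancy from per-chemistry category counts
#'
#' Derives the complete keep/discard arithmetic from per-chemistry counts:
#' potentially noisy probes (total minus high-quality), kept probes
#' (high-quality plus rescued), discarded probes, the removal fraction
#' under the recommended policy, and the aggressive removal fraction under
#' an everything-flagged-goes policy. When a unique-category table with a
#' kept column is supplied, its kept sum is cross-checked against the
#' rescued total and any mismatch is reported in `inconsistencies` (the
#' published tables contain such transcription-level quirks).
#'
#' @param totals,high_quality,rescued numeric vectors `c(I = , II = )`.
#' @param unique_category optional data.frame with a `kept` column.
#' @param any_overlap optional data.frame with `type_i`, `type_ii`,
#'   `printed_total` columns; chemistry sums are checked against the
#'   printed totals.
#' @return list with per-chemistry vectors `noisy`, `kept`, `discarded`,
#'   scalars `total_probes`, `kept_total`, `discarded_total`,
#'   `rescued_total`, `high_quality_total`, `noisy_total`,
#'   `removal_fraction_pct`, `aggressive_fraction_pct`, and a character
#'   vector `inconsistencies`.
#' @examples
#' ref <- hm450kReferenceCounts()
#' acc <- arrayAccounting(ref$totals, ref$high_quality, ref$rescued,
#'                        ref$unique_category, ref$any_overlap)
#' round(acc$removal_fraction_pct)  # 39
#' @export
arrayAccounting <- function(totals, high_quality, rescued,
                            unique_category = NULL, any_overlap = NULL) {
    stopifnot(all(c("I", "II") %in% names(totals)),
              all(c("I", "II") %in% names(high_quality)),
              all(c("I", "II") %in% names(rescued)))
    noisy <- totals - high_quality
    kept <- high_quality + rescued
    discarded <- totals - kept
    inc <- character(0)
    if (!is.null(unique_category)) {
        kept_sum <- sum(unique_category$kept)
        if (kept_sum != sum(rescued))
            inc <- c(inc, sprintf(
                "unique-category kept column sums to %d, rescued total is %d",
                kept_sum, sum(rescued)))
        ucat_sum <- c(I = sum(unique_category$type_i),
                      II = sum(unique_category$type_ii))
        for (ch in c("I", "II"))
            if (ucat_sum[ch] != noisy[ch])
                inc <- c(inc, sprintf(
                    "unique categories (type %s) sum to %d, noisy total is %d",
                    ch, ucat_sum[ch], noisy[ch]))
    }
    if (!is.null(any_overlap)) {
        row_sum <- any_overlap$type_i + any_overlap$type_ii
        bad <- which(row_sum != any_overlap$printed_total)
        for (b in bad)
            inc <- c(inc, sprintf(
                "any-overlap row '%s': chemistry split sums to %d, printed total is %d",
                any_overlap$category[b], row_sum[b],
                any_overlap$printed_total[b]))
    }
    list(noisy = noisy, kept = kept, discarded = discarded,
         total_probes = sum(totals),
         kept_total = sum(kept),
         discarded_total = sum(discarded),
         rescued_total = sum(rescued),
         high_quality_total = sum(high_quality),
         noisy_total = sum(noisy),
         removal_fraction_pct = 100 * sum(discarded) / sum(totals),
         aggressive_fraction_pct = 100 * sum(noisy) / sum(totals),
         inconsistencies = inc)
}
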