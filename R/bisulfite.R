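#' Build the reduced-complexity bisulfite genome
#'
#' Produces, per chromosome, the fully converted forward text (every C
#' replaced by T) and the converted reverse-complement text
#' (reverse-complement first, then C to T). Full conversion is
#' methylation-blind: probe queries carry a C-or-T wildcard at CpG-context
#' positions, so methylated and unmethylated templates match identically.
#' `N` passes through unchanged and never matches any query letter.
#' Conversion is idempotent: converting an already converted text again is
#' the identity.
#'
#' @param genome a named `DNAStringSet` or FASTA file path.
#' @param sourceId identifier recorded for provenance.
#' @return a [BisulfiteGenome-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' bisulfiteConvert(g)
#' @export
bisulfiteConvert <- function(genome, sourceId = "genome") {
    genome <- .asGenome(genome)
    fwd <- Biostrings::DNAStringSet(chartr("C", "T", as.character(genome)))
    rev <- Biostrings::DNAStringSet(chartr("C", "T", as.character(
        Biostrings::reverseComplement(genome))))
    names(fwd) <- names(genome)
    names(rev) <- names(genome)
    new("BisulfiteGenome", forward = fwd, reverse = rev, sourceId = sourceId)
}

#' @rdname bisulfiteConvert
#' @param x a `BisulfiteGenome`
#' @export
convertedForward <- function(x) x@forward

#' @rdname bisulfiteConvert
#' @export
convertedReverse <- function(x) x@reverse

#' Convert a probe sequence to its bisulfite-space query
#'
#' Cytosines outside CpG context are fixed to T (they are always read as T
#' after conversion); CpG-context cytosines become the two-letter wildcard
#' `Y` (C or T, methylation-dependent); the degenerate `R` bases of type II
#' probes match A or G. The query is matched against converted genome texts
#' with pattern ambiguity enabled and subject letters literal, so genomic
#' `N` never matches.
#'
#' @param probe_seq a 50-character probe sequence over `{A,C,G,T,R}`.
#' @return a `DNAString` of length 50 over `{A,G,T,Y,R}`.
#' @examples
#' as.character(probeBisulfiteQuery("TTCATTCGAT"))  # "TTTATTYGAT"
#' @export
probeBisulfiteQuery <- function(probe_seq) {
    probe_seq <- toupper(probe_seq)
    if (grepl("[^ACGTR]", probe_seq))
        stop("probe sequence contains letters outside {A,C,G,T,R}")
    chars <- strsplit(probe_seq, "")[[1]]
    is_c <- chars == "C"
    # CpG context inside the probe: C followed by G (or a degenerate R,
    # which stands for the G of a body CpG in type II probes)
    nxt <- c(chars[-1], "")
    cpg <- is_c & nxt %in% c("G", "R")
    chars[cpg] <- "Y"
    chars[is_c & !cpg] <- "T"
    Biostrings::DNAString(paste(chars, collapse = ""))
}

#' Count genomic hits of a bisulfite-space query
#'
#' Scans both converted strand texts of every chromosome for occurrences of
#' the query (exact by default; `max_mismatch` allows substitutions). The
#' result is independent of chromosome iteration order. Hit locations are
#' reported as 0-based forward-strand starts with the strand text they were
#' found on, capped at `max_locations`; the count itself is always exact.
#'
#' @param query a `DNAString`/character bisulfite-space query (length 50 in
#'   normal use), possibly containing `Y`/`R` wildcards.
#' @param bsgenome a [BisulfiteGenome-class].
#' @param max_mismatch non-negative integer.
#' @param max_locations cap on the reported location list.
#' @return a list with `hit_count` (integer) and `hit_locations`
#'   (data.frame `chrom`, `start0`, `strand`).
#' @export
countGenomicHits <- function(query, bsgenome, max_mismatch = 0L,
                             max_locations = 16L) {
    if (!is(bsgenome, "BisulfiteGenome"))
        stop("bsgenome must be a BisulfiteGenome")
    if (length(bsgenome@forward) == 0L)
        stop("empty genome")
    if (is.character(query)) query <- Biostrings::DNAString(query)
    n <- 0L
    locs <- list()
    for (chrom in names(bsgenome@forward)) {
        L <- length(bsgenome@forward[[chrom]])
        mf <- Biostrings::matchPattern(
            query, bsgenome@forward[[chrom]], max.mismatch = max_mismatch,
            fixed = c(pattern = FALSE, subject = TRUE))
        if (length(mf)) {
            n <- n + length(mf)
            locs[[length(locs) + 1L]] <- data.frame(
                chrom = chrom, start0 = BiocGenerics::start(mf) - 1L,
                strand = "+", stringsAsFactors = FALSE)
        }
        mr <- Biostrings::matchPattern(
            query, bsgenome@reverse[[chrom]], max.mismatch = max_mismatch,
            fixed = c(pattern = FALSE, subject = TRUE))
        if (length(mr)) {
            n <- n + length(mr)
            # map position in the reverse text back to forward coordinates
            locs[[length(locs) + 1L]] <- data.frame(
                chrom = chrom,
                start0 = L - (BiocGenerics::start(mr) - 1L) -
                    length(query),
                strand = "-", stringsAsFactors = FALSE)
        }
    }
    locs <- if (length(locs)) do.call(rbind, locs) else
        data.frame(chrom = character(0), start0 = integer(0),
                   strand = character(0), stringsAsFactors = FALSE)
    locs <- locs[order(locs$chrom, locs$start0, locs$strand), , drop = FALSE]
    rownames(locs) <- NULL
    list(hit_count = n,
         hit_locations = utils::head(locs, max_locations))
}

#' Flag probes matching more than one genomic location
#'
#' Converts every probe to bisulfite space, counts its hits over both
#' converted strand texts, and reports the multi-mapping set (hit count
#' greater than 1). Probes with zero hits are reported separately as
#' unmappable; probes on chromosomes absent from the genome are still
#' scanned genome-wide (a probe is a sequence, not a coordinate, for this
#' purpose).
#'
#' @param probes a [ProbeSet-class].
#' @param bsgenome a [BisulfiteGenome-class].
#' @param max_mismatch allowed substitutions per hit (default exact).
#' @return a list with `multimap` (character probe ids), `unmappable`
#'   (character probe ids) and `hits` (data.frame `probe_id`, `hit_count`,
#'   `locations` as a "chrom:start0:strand" comma string).
#' @export
flagMultimappers <- function(probes, bsgenome, max_mismatch = 0L) {
    pd <- probes@probeData
    hit_count <- integer(nrow(pd))
    locs <- character(nrow(pd))
    for (i in seq_len(nrow(pd))) {
        h <- countGenomicHits(probeBisulfiteQuery(pd$probe_seq[i]),
                              bsgenome, max_mismatch = max_mismatch)
        hit_count[i] <- h$hit_count
        locs[i] <- paste(sprintf("%s:%d:%s", h$hit_locations$chrom,
                                 h$hit_locations$start0,
                                 h$hit_locations$strand), collapse = ",")
    }
    hits <- data.frame(probe_id = pd$probe_id, hit_count = hit_count,
                       locations = locs, stringsAsFactors = FALSE)
    list(multimap = pd$probe_id[hit_count > 1L],
         unmappable = pd$probe_id[hit_count == 0L],
         hits = hits)
}
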