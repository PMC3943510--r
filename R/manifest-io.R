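#' Column-name dialect for probe manifest files
#'
#' Maps the package's canonical probe fields to the column names used in a
#' manifest CSV. Defaults follow the Illumina HM450K manifest.
#'
#' @param probe_id,design_type,chrom,cpg_pos,strand,probe_seq,source_seq
#'   column names in the file; `source_seq` may be absent from the file.
#' @return a named character vector usable as the `dialect` argument of
#'   [readManifest()].
#' @export
manifestDialect <- function(probe_id = "IlmnID",
                            design_type = "Infinium_Design_Type",
                            chrom = "CHR", cpg_pos = "MAPINFO",
                            strand = "Strand",
                            probe_seq = "AlleleA_ProbeSeq",
                            source_seq = "SourceSeq") {
    c(probe_id = probe_id, design_type = design_type, chrom = chrom,
      cpg_pos = cpg_pos, strand = strand, probe_seq = probe_seq,
      source_seq = source_seq)
}

#' Read and validate a probe manifest CSV
#'
#' Parses one probe record per row. Rows violating the record invariants
#' (sequence length 50, alphabet, R only in type II, positive coordinates)
#' are rejected with row-level diagnostics and reported in the
#' `"rejected"` attribute; in strict mode any bad row is an error.
#'
#' Strand is normalised: Illumina's `F`/`R` are read as `+`/`-`.
#'
#' @param path CSV file path.
#' @param dialect named character vector mapping canonical fields to file
#'   columns; see [manifestDialect()].
#' @param strict logical; if `TRUE`, invalid rows abort the parse.
#' @return a [ProbeSet-class]; attribute `"rejected"` holds a data.frame of
#'   rejected rows (`probe_id`, `row`, `reason`), and `"n_parsed"` the total
#'   row count read from the file.
#' @export
readManifest <- function(path, dialect = manifestDialect(), strict = FALSE) {
    if (!file.exists(path)) stop("manifest file not found: ", path)
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    mandatory <- setdiff(names(dialect), "source_seq")
    miss <- mandatory[!dialect[mandatory] %in% colnames(raw)]
    if (length(miss))
        stop("manifest is missing mandatory columns: ",
             paste(dialect[miss], collapse = ", "))
    df <- data.frame(
        probe_id = as.character(raw[[dialect[["probe_id"]]]]),
        design_type = toupper(as.character(raw[[dialect[["design_type"]]]])),
        chrom = as.character(raw[[dialect[["chrom"]]]]),
        cpg_pos = suppressWarnings(
            as.integer(raw[[dialect[["cpg_pos"]]]])),
        strand = as.character(raw[[dialect[["strand"]]]]),
        probe_seq = toupper(as.character(raw[[dialect[["probe_seq"]]]])),
        stringsAsFactors = FALSE)
    if (dialect[["source_seq"]] %in% colnames(raw))
        df$source_seq <- toupper(as.character(raw[[dialect[["source_seq"]]]]))
    df$strand[df$strand %in% c("F", "f")] <- "+"
    df$strand[df$strand %in% c("R", "r")] <- "-"

    reason <- rep(NA_character_, nrow(df))
    flag <- function(bad, why) {
        bad <- bad & is.na(reason)
        reason[bad] <<- why
    }
    flag(nchar(df$probe_seq) != 50L, "probe_seq length != 50")
    flag(grepl("[^ACGTR]", df$probe_seq), "probe_seq has non-ACGTR letters")
    flag(grepl("R", df$probe_seq) & df$design_type == "I",
         "R base in type I probe")
    flag(!df$design_type %in% c("I", "II"), "design_type not I/II")
    flag(!df$strand %in% c("+", "-"), "strand not +/-")
    flag(is.na(df$cpg_pos) | df$cpg_pos < 1L, "cpg_pos missing or < 1")
    flag(is.na(df$chrom) | nchar(df$chrom) == 0, "empty chrom")

    bad <- !is.na(reason)
    rejected <- data.frame(probe_id = df$probe_id[bad],
                           row = which(bad), reason = reason[bad],
                           stringsAsFactors = FALSE)
    if (strict && nrow(rejected))
        stop("invalid manifest rows: ",
             paste(sprintf("%s (row %d: %s)", rejected$probe_id,
                           rejected$row, rejected$reason), collapse = "; "))
    ps <- ProbeSet(df[!bad, , drop = FALSE])
    attr(ps, "rejected") <- rejected
    attr(ps, "n_parsed") <- nrow(df)
    ps
}

#' Write a ProbeSet back to manifest CSV
#'
#' Inverse of [readManifest()] under the same dialect; a parse/write/parse
#' round trip is the identity on valid manifests.
#'
#' @param probes a [ProbeSet-class].
#' @param path output CSV path.
#' @param dialect see [manifestDialect()].
#' @return `path`, invisibly.
#' @export
writeManifest <- function(probes, path, dialect = manifestDialect()) {
    pd <- as.data.frame(probes@probeData)
    out <- data.frame(pd$probe_id, pd$design_type, pd$chrom, pd$cpg_pos,
                      ifelse(pd$strand == "+", "F", "R"), pd$probe_seq,
                      stringsAsFactors = FALSE, check.names = FALSE)
    nm <- dialect[c("probe_id", "design_type", "chrom", "cpg_pos", "strand",
                    "probe_seq")]
    if (!is.null(pd$source_seq)) {
        out$source_seq <- pd$source_seq
        nm <- c(nm, dialect[["source_seq"]])
    }
    colnames(out) <- nm
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

# 0-based footprint start for each probe under a convention.
# "sbe" (default): type I probes cover the interrogated C at the probe
# terminus and extend in the strand direction; type II probes terminate one
# base short of the C (the single-base extension reads the C), so their
# footprint abuts the CpG on the G side.
.footprintStart0 <- function(design_type, strand, cpg_pos,
                             convention = "sbe") {
    convention <- match.arg(convention, c("sbe", "typeII_covers"))
    p0 <- cpg_pos - 1L  # 0-based position of the C
    start0 <- integer(length(cpg_pos))
    ii <- design_type == "I"
    if (convention == "typeII_covers") ii <- ii | !ii  # all behave like type I
    plus <- strand == "+"
    start0[ii & plus] <- p0[ii & plus]
    start0[ii & !plus] <- p0[ii & !plus] - 48L
    start0[!ii & plus] <- p0[!ii & plus] + 1L
    start0[!ii & !plus] <- p0[!ii & !plus] - 49L
    start0
}

#' Genomic hybridization footprints of probes
#'
#' Computes the 50-bp forward-strand interval each probe hybridizes, anchored
#' at the interrogated CpG. Under the default `"sbe"` convention a type I
#' probe covers the interrogated C at its terminal position and extends in
#' the strand direction (plus-strand probe at `cpg_pos = 1001`: interval
#' 1001..1050 in 1-based coordinates), while a type II probe terminates one
#' base short of the C, its footprint abutting the CpG. The footprint always
#' contains or abuts the CpG dinucleotide and has length 50 on either strand.
#'
#' @param probes a [ProbeSet-class].
#' @param convention `"sbe"` (default) or `"typeII_covers"` (type II probes
#'   treated like type I, covering the C).
#' @return a `GRanges` named by probe id, with strand set from the manifest.
#' @export
probeFootprints <- function(probes, convention = "sbe") {
    pd <- probes@probeData
    start0 <- .footprintStart0(pd$design_type, pd$strand, pd$cpg_pos,
                               convention)
    if (any(start0 < 0L))
        stop("footprint extends before position 1 for probes: ",
             paste(pd$probe_id[start0 < 0L], collapse = ", "))
    gr <- GenomicRanges::GRanges(
        seqnames = pd$chrom,
        ranges = IRanges::IRanges(start = start0 + 1L, width = 50L),
        strand = pd$strand)
    names(gr) <- pd$probe_id
    gr
}

#' Check probe sequences against a reference genome in bisulfite space
#'
#' For each probe the declared-strand genomic footprint is extracted,
#' bisulfite-converted, and compared with the probe's bisulfite-space query
#' (non-CpG C fixed to T, CpG-context C matched as C-or-T, degenerate R
#' matched as A-or-G). The verdict is `"consistent"` if the probe matches on
#' its declared strand, `"strand_flipped"` if it matches only the opposite
#' strand at the same locus, and `"mismatch"` otherwise. Probes on
#' chromosomes absent from the genome, or whose footprint exceeds the
#' chromosome end, receive verdict `"unevaluable"`.
#'
#' @param probes a [ProbeSet-class].
#' @param genome a named `DNAStringSet` (or FASTA path) of the reference.
#' @param convention footprint convention; see [probeFootprints()].
#' @return a data.frame with `probe_id` and `verdict`.
#' @export
verifyProbes <- function(probes, genome, convention = "sbe") {
    genome <- .asGenome(genome)
    pd <- probes@probeData
    # does the probe match assuming it hybridizes strand s?
    checkOn <- function(i, s) {
        chrom <- pd$chrom[i]
        if (!chrom %in% names(genome)) return(NA)
        s0 <- .footprintStart0(pd$design_type[i], s, pd$cpg_pos[i],
                               convention)
        if (s0 < 0L || s0 + 50L > length(genome[[chrom]])) return(NA)
        fp <- Biostrings::subseq(genome[[chrom]], s0 + 1L, s0 + 50L)
        if (s == "-") fp <- Biostrings::reverseComplement(fp)
        .bisMatches(probeBisulfiteQuery(pd$probe_seq[i]), fp)
    }
    verdict <- vapply(seq_len(nrow(pd)), function(i) {
        declared <- checkOn(i, pd$strand[i])
        if (is.na(declared)) return("unevaluable")
        if (declared) return("consistent")
        flipped <- checkOn(i, setdiff(c("+", "-"), pd$strand[i]))
        if (isTRUE(flipped)) "strand_flipped" else "mismatch"
    }, character(1))
    data.frame(probe_id = pd$probe_id, verdict = verdict,
               stringsAsFactors = FALSE)
}

# does the wildcard query match the bisulfite conversion of this footprint?
.bisMatches <- function(query, footprint) {
    conv <- Biostrings::DNAString(chartr("C", "T", as.character(footprint)))
    length(Biostrings::matchPattern(
        query, conv, fixed = c(pattern = FALSE, subject = TRUE))) > 0L
}

.asGenome <- function(genome) {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    if (is(genome, "DNAStringSet")) {
        names(genome) <- sub("\\s.*$", "", names(genome))
        return(genome)
    }
    stop("genome must be a DNAStringSet or a FASTA file path")
}
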