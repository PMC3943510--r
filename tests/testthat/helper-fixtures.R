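# Shared seeded fixture, generated once per test run and reused across
# test files (generation + annotation of the toy study costs a few
# seconds; tests only read from it).

.fixture_cache <- new.env(parent = emptyenv())

sharedFixture <- function() {
    if (is.null(.fixture_cache$fx))
        .fixture_cache$fx <- generateFixture(fixtureConfig(seed = 42L))
    .fixture_cache$fx
}

sharedFixtureDir <- function() {
    if (is.null(.fixture_cache$dir)) {
        dir <- file.path(tempdir(), "probeqc-shared-fixture")
        writeFixture(sharedFixture(), dir)
        .fixture_cache$dir <- dir
    }
    .fixture_cache$dir
}

# fully annotated view of the shared fixture
sharedAnnotation <- function() {
    if (is.null(.fixture_cache$ann)) {
        fx <- sharedFixture()
        dir <- sharedFixtureDir()
        bsg <- bisulfiteConvert(fx$genome)
        sites <- readWgbsSites(file.path(dir, "wgbs.bedgraph"))
        paired <- pairProbeWgbs(fx$probes, sites, fx$betas)
        flags <- annotateProbes(fx$probes, bsg, fx$repeats, fx$variants,
                                fx$genome, paired = paired)
        .fixture_cache$ann <- list(fx = fx, bsg = bsg, sites = sites,
                                   paired = paired, flags = flags)
    }
    .fixture_cache$ann
}

# minimal hand-built flags row for decision-rule tests
flagsRow <- function(probe_id = "p1", design_type = "I", multimap = FALSE,
                     repeat_overlap = FALSE, indel_overlap = FALSE,
                     snp_at_cpg_c = FALSE, snp_at_cpg_g = FALSE,
                     body_snps_total = 0L, body_snps_bisokay = 0L,
                     max_avg_het = NA_real_, unknown_factor = NA) {
    data.frame(probe_id = probe_id, design_type = design_type,
               multimap = multimap, repeat_overlap = repeat_overlap,
               indel_overlap = indel_overlap, snp_at_cpg_c = snp_at_cpg_c,
               snp_at_cpg_g = snp_at_cpg_g,
               body_snps_total = body_snps_total,
               body_snps_bisokay = body_snps_bisokay,
               body_snps_effective = body_snps_total - body_snps_bisokay,
               max_avg_het = max_avg_het, unknown_factor = unknown_factor,
               stringsAsFactors = FALSE)
}

# small well-formed manifest data.frame
toyManifestDf <- function() {
    data.frame(
        IlmnID = c("cg000001", "cg000002", "cg000003"),
        Infinium_Design_Type = c("I", "II", "I"),
        CHR = c("chr1", "chr1", "chr2"),
        MAPINFO = c(1001L, 2001L, 501L),
        Strand = c("F", "R", "F"),
        AlleleA_ProbeSeq = c(
            paste(rep("ACGTA", 10), collapse = ""),
            paste(rep("ACGTR", 10), collapse = ""),
            paste(rep("TTGAT", 10), collapse = "")),
        stringsAsFactors = FALSE)
}
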