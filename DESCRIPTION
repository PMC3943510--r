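Package: probeQC
Title: Quality Annotation and Filtering of HM450K Methylation Array Probes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates Illumina HumanMethylation450 (HM450K) style probes for
    genomic factors that compromise methylation measurement: multi-mapping in
    the reduced-complexity bisulfite genome, repeat overlap, INDEL overlap,
    SNPs at the interrogated CpG and in the probe body (with the
    bisulfite-space rescue rule for C/T substitutions), and discordance
    against matched whole-genome bisulfite sequencing. Applies a configurable
    keep/discard decision workflow with study-type presets, reports
    category-level noise statistics (median absolute beta differences,
    Pearson correlation, Wilcoxon rank-sum tests against the high-quality
    background, 2-D beta density matrices, per-probe standard deviations),
    and produces per-category filtering accountancy. Includes a seeded
    synthetic-data generator that emulates all required inputs at toy scale
    with known ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, MethylationArray, QualityControl, Preprocessing
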