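Package: medipdmr
Title: Differential Methylation Analysis for MeDIP-Seq Peak Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of MeDIP-seq methylation peak data from
    placental samples across gestational age: consensus peak construction
    from technical replicates, negative-binomial GLM Wald testing of peak
    counts against preterm-birth status (dichotomous) or gestational age
    (continuous) with Benjamini-Hochberg correction and
    rejection-maximizing independent filtering, nearest-gene and genomic
    category annotation with CpG island/shore/shelf context, 500-bp
    window-based genomic feature enrichment scores stratified by
    methylation direction, and comparative gene-set overlap analysis.
    Includes a seeded synthetic-data generator emulating the study design
    (9 individuals, 3 technical replicates, negative-binomial counts with
    planted effects) so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
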