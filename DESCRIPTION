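Package: lineamp
Title: Lineage-Specific Amplicon Driver Discovery from Integrated Copy
    Number and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of tiling-path array comparative genomic
    hybridization (aCGH) and gene expression cohorts to identify
    lineage-specific amplicon driver genes. Provides replicate-level quality
    control, exact dynamic-programming segmentation of log2 ratio profiles,
    three-state copy-number calling, high-level amplification detection with
    run-length thresholds, two-cohort alteration-disparity testing (exact
    3x2 Fisher tests with Benjamini-Hochberg correction, region merging and
    frequency filters), copy-number/expression dosage integration (windowed
    Z-score Spearman correlation and gain-versus-neutral rank tests), a
    multi-criterion candidate-oncogene filtering cascade, a permutation-based
    SAM-style expression signature module, and a synthetic cohort simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
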