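Package: scads
Title: Single-Cell ATAC-Seq Disease Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates GWAS summary statistics with single-cell ATAC-seq
    count data to prioritise disease-relevant cells. Fits a grade-of-membership
    (topic) model to the sparse cell-by-region count matrix via Poisson
    non-negative matrix factorisation, derives per-topic open-chromatin variant
    annotations with a GC-aware baseline and a log-fold-change test, estimates
    per-topic heritability enrichment by stratified LD-score regression with
    block-jackknife standard errors, and reconstructs a calibrated per-cell
    disease-relevance score with analytic variance, z-score, p-value and
    Benjamini-Hochberg FDR. Ships simulators for synthetic scATAC-seq counts,
    block-LD genotype panels, annotation-stratified GWAS traits and Bernoulli
    pseudobulk accessibility, plus downstream variant-accessibility
    correlation, regulon enrichment and fine-mapping prior export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse
Config/testthat/edition: 3
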