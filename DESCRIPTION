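Package: celltrait
Title: Cell-Type Expression Specificity and Genetic Liability Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links single-cell RNA-seq cell populations to common and rare
    variant genetic liability. Computes EWCE-style per-gene expression
    specificity scores over cell populations, gene-level GWAS association
    statistics under the SNP-wise mean model with an LD-aware quadratic-form
    null, competitive gene-set enrichment with technical covariates,
    stratified LD-score regression with block-jackknife coefficient tests,
    per-cell trait-association scores regressed along a developmental
    pseudotime trajectory, one-sided rank tests of fine-mapped gene
    specificity, and Firth penalized-likelihood burden tests of rare
    protein-truncating variants with full genotype, variant, and sample
    quality control. A synthetic-data module generates every input with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
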