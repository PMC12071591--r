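Package: admixprs
Title: Polygenic Risk Score Validation in Admixed Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating breast-cancer polygenic risk scores (PRS) in
    admixed case-control cohorts: parsing of PGS-Catalog-style scoring files and
    VCF genotype/dosage matrices, variant filtering and effect-allele matching,
    zero-to-one normalized and control-standardized scoring, cohort quality
    control (first-degree relatedness pruning, monogenic carrier exclusion,
    continental-ancestry grouping), genotype principal components as covariates,
    PC-adjusted odds ratios per standard deviation and per decile or percentile
    interval, AUC by stratified holdout and cross-validation, imputed-versus-
    sequenced score concordance, and a liability-model simulator of admixed
    cohorts with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
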