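Package: rarelasso
Title: Rare-Variant Collapsing and L1-Penalized Multimarker Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-level collapsing of rare sequence variants (proportion
    coding, data-adaptive sum, and weighted sum), L1-penalized multimarker
    regression with unpenalized covariates and optional separate penalties
    for nonsynonymous and synonymous collapsed terms, and evaluation of
    collapsing methods across phenotype replicates by selection
    consistency, cross-replicate prediction error, and ROC analysis
    against a known truth set. Includes a simulator of mini-exome style
    genotype and multi-replicate phenotype data with a liability-threshold
    disease model, plus readers and writers for VCF and delimited formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
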