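Package: qsmartr
Title: Integrated Structure and Mechanism-of-Action Activity Relationship
    Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits QSMARt models: sparse linear activity models over fused
    blocks of molecular descriptors and per-gene log fold-change features,
    with a block-wise power transformation of the design matrix and an
    L1-penalized (lasso) estimator. Provides repeated stratified
    random-split validation (RSVA), external validation statistics
    (Q2F1/Q2F2/Q2F3, concordance correlation), a consensus applicability
    domain (leverage/Williams, standardization, Euclidean and city-block
    distance, k-nearest neighbours, Insubria graph), grid search over the
    transformation exponents with eligibility-based final-model selection,
    a synthetic-data generator with planted sparse signals, and bundled
    published human-serum-albumin binding models as callable predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
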