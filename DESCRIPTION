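Package: countsig
Title: Covariate Transformations for Penalized-Regression Gene Signatures
    from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how transformations of RNA-Seq count
    covariates (log, variance-stabilizing, Box-Cox, standardization and
    their compositions, ranks, Blom normal scores) affect gene-signature
    building with componentwise likelihood-based boosting and the lasso.
    Provides a negative-binomial count simulator with mean-variance
    dependency, correlation blocks and extreme values; median-of-ratios
    normalization with low-count filtering and per-gene truncation;
    componentwise likelihood-based boosting for logistic and Cox models
    with mandatory unpenalized covariates; selection ROC curves with
    partial area up to ten false positives; censoring-weighted Brier
    prediction-error curves with the 0.632+ estimator, integrated
    prediction error, and added value over a clinical-only model; and
    drivers for the identification and prediction studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
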