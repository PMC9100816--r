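Package: NeuralLasso
Title: Banded Neural Lasso for Whole-Genome Prediction with Local Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of continuous traits from genome-ordered SNP
    dosage matrices with a banded, single-layer, ReLU-activated, L1-penalized
    regression model that captures epistatic interactions among neighboring
    markers. Includes the bisection search for the penalty weight on a
    validation split, full-batch Adam training with a cosine learning-rate
    schedule, classical baselines (elastic net by coordinate descent, GBLUP
    with spectral REML variance components and SNP heritability), a repeated
    k-fold cross-validation harness scoring Pearson prediction accuracy,
    a synthetic genotype/trait simulator with local linkage disequilibrium
    and neighborhood epistasis, marker QC filters, and readers for delimited
    dosage tables and PLINK .raw files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
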