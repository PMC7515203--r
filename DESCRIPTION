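Package: adipomr
Title: Mendelian Randomization and Adipose Transcriptomics Modelling of
    Insulin Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the causal role of obesity in prediabetes
    and insulin resistance and the contribution of adipose tissue to
    systemic insulin sensitivity. Implements two-sample Mendelian
    randomization with inverse-variance-weighted and Egger estimators,
    Cochran's Q heterogeneity testing, and an MR-PRESSO style resampling
    procedure for pleiotropy control; bulk RNA-seq cell-type deconvolution
    against a single-nucleus reference using cross-subject-variance
    weighted non-negative least squares with a bulk/pseudo-bulk
    concordance filter; mitochondrial gene-expression quantification with
    bias-aware technical-factor correction; and an elastic-net model that
    predicts the Matsuda insulin-sensitivity index from adipose features.
    A synthetic-data module generates every input with known ground truth
    so the full pipeline is testable without cohort access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
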