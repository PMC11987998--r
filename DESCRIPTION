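Package: threestage
Title: Three-Stage Heuristic Grid Search for Deep Feedforward Clinical
    Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing deep feedforward neural network (DFNN)
    models that predict future clinical risk (e.g. breast cancer
    metastasis) from integer-coded tabular predictors under a limited
    compute budget. Implements a heuristic three-stage grid-search
    mechanism: single-hyperparameter sweeps with proper-value extraction,
    a full grid with per-setting running-time (RTPS) estimation, and
    refinement cycles of sweet-spot grid search (SSGS), out-of-the-local-
    optimum (OLO) reseeding and randomized grid search (RGS). Includes
    search-space combinatorics and budget arithmetic, a synthetic
    EHR-like data generator with a planted logistic signal, stratified
    5-fold cross-validated AUC evaluation of a compact built-in DFNN
    trainer, group and mid-point performance analytics, and Shapley-value
    explanation machinery (exact and sampled estimators with k-means
    background data), including a hyperparameters-as-features importance
    analysis of grid-search logs via a random-forest surrogate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
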