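Package: sepsiscp
Title: Mondrian Conformal Prediction for ICU Sepsis Mortality Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Class-conditional (Mondrian) inductive conformal prediction
    wrapped around a gradient-boosted in-hospital mortality risk model for
    ICU sepsis cohorts. Provides a synthetic cohort generator with a latent
    severity factor, leakage-safe preprocessing (repeated-measure
    aggregation, one-hot encoding, k-nearest-neighbour BMI imputation,
    train-only standardisation), per-class calibrated p-values and typed
    prediction regions (empty/single/multiple), Monte-Carlo Shapley feature
    attribution, and evaluation utilities (AUC, Brier score, reliability
    curves, stratified bootstrap confidence intervals, region tabulations
    and error-versus-significance curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xgboost,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
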