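Package: anemomap
Title: Model-Based Geostatistical Mapping of Anemia Severity in Women of
    Reproductive Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable implementation of the model-based
    geostatistics workflow used to map mild, moderate and severe anemia
    prevalence in women of reproductive age: hemoglobin adjustment and WHO
    severity classification, stacked-ensemble covariates, continuation-ratio
    binomial Gaussian-process models with Matern-AR1 Kronecker space-time
    covariance, posterior-draw post-estimation (population-weighted
    aggregation, counts, years lived with disability), raking calibration to
    a national series, logit-space trend projection against the WHO Global
    Nutrition Target, and spatially stratified cross-validation. A synthetic
    data generator with known ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    glmnet,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
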