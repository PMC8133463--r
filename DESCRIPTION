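Package: climenvelope
Title: Climate-Envelope Species Distribution Modelling with Spatially
    Blocked Validation and Scenario Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits climate-envelope species distribution models for
    threshold-limited ranges: assembly of presence, transect-absence and
    distance-constrained pseudo-absence records; five model algorithms
    (GLM, GAM, MaxEnt-equivalent penalised regression, boosted regression
    trees, random forests) behind a single fit/predict/response-curve
    contract; radial-segment leave-one-out cross-validation with AUC-ROC
    scoring and delta-AUC variable importance; max-kappa threshold
    binarisation; and GCM-by-RCP future projection with
    latitude-corrected range areas and percent-left summaries. Includes a
    synthetic-world generator that emulates spatially autocorrelated
    bioclimate fields with a cool-dry core, so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mgcv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
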