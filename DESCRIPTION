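Package: seabedmp
Title: Seabed Microlitter Storage-Potential Mapping with Boosted Regression Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for modelling the microlitter storage
    potential of seabed sediments from physical seabed predictors.
    Implements stochastic gradient boosting with regression-stump base
    learners and squared-error loss, model selection by replicated
    leave-one-out mean absolute error with permutation-importance-ordered
    forward selection, empirical semivariogram diagnostics of model
    residuals, projection of the selected model onto a prediction grid,
    and overlay of the predicted surface with source and receptor polygon
    layers to classify exposure risk. Includes a synthetic-data generator
    that emulates the statistical structure of seabed microplastic survey
    data (spatially clustered stations, overdispersed counts) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    geosphere,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
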