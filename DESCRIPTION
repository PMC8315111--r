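Package: bartpm
Title: Bayesian Additive Regression Trees for PM2.5 Component Exposure Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sum-of-trees Bayesian additive regression trees (BART) fitted by
    Metropolis-within-Gibbs backfitting, with coverage-calibrated tuning,
    ordinary / leave-monitor-out / k-means-cluster cross-validation,
    split-count variable importance, partial dependence curves, and gridded
    prediction with uncertainty. Includes a synthetic monitor-network data
    generator that emulates the sparse speciation-monitoring designs used for
    daily PM2.5 component (EC, OC, sulfate, nitrate) exposure models, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
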