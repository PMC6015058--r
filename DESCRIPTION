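Package: platehit
Title: Bayesian Nonparametric Hit Calling for Multi-Plate Compound Screens
Version: 0.1.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@example.org",
           role = c("aut", "cre"))
Description: Hit identification for multi-plate high-throughput compound
    screens. Fits a two hierarchical-Dirichlet-process Gaussian mixture
    model over active and inactive compounds across all plates at once by
    blocked Gibbs sampling, yielding per-compound posterior hit
    probabilities with Bayesian false discovery rate control. Also
    provides the classical per-plate normalization baselines (normalized
    percent inhibition, Z-score, B-score via Tukey median polish, R-score
    via robust IRLS), a synthetic screen generator with matrix-normal
    plate-effect noise, ROC/AUC evaluation utilities including the
    threshold-sweep AUC for binary predictors, MCMC diagnostics, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
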