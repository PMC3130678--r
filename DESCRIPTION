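Package: peakshift
Title: Multi-Peak Ornstein-Uhlenbeck Models of Ecomorphological
    Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of adaptive radiations on phylogenies:
    generalized Procrustes analysis of 2-D landmark/semilandmark data with
    sliding, shape principal components with Horn's parallel analysis,
    phylogenetic generalized least squares regression under the
    Martins-Hansen exponential covariance, disparity-through-time curves
    with Brownian-motion null envelopes, maximum-likelihood ancestral
    state estimation and regime painting, and maximum-likelihood fitting
    of Brownian-motion and multi-peak multivariate Ornstein-Uhlenbeck
    (Hansen) models with AICc/SIC model selection and parametric
    bootstrap confidence regions for adaptive optima.  Includes
    simulators for trees, regime histories, Ornstein-Uhlenbeck traits,
    diet-rank tables and landmark configurations so every stage can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
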