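Package: mtess
Title: Multitrait Bayesian Variable Selection for Exposome Data with
    Stability-Calibrated Conditional-Independence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exposome-wide association analysis of correlated
    chemical exposures and multivariate continuous outcomes. Implements an
    evolutionary stochastic search MCMC sampler with parallel tempering for
    Bayesian variable selection under a conjugate matrix-variate g-prior,
    posterior summaries (model posterior probabilities, marginal posterior
    probabilities of inclusion, permutation-based empirical FDR thresholds,
    Bayes factors and ratios of Bayes factors, effect-size posteriors),
    stability-calibrated graphical LASSO networks with per-family error rate
    control and Louvain community detection, limit-of-detection and iterative
    missing-data imputation, and a synthetic cohort generator emulating
    hair-biomonitoring study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    rpart,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
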