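Package: credpair
Title: Credible Subgroup Pairs for Heterogeneous Treatment Effects with
    Binary Endpoints
Version: 1.0.0
Authors@R: person("credpair", "developers", email = "credpair@example.org",
    role = c("aut", "cre"))
Description: Identifies the covariate profiles of trial participants with
    sufficient evidence of treatment benefit (or of no benefit) from a
    randomised trial with a binary endpoint. Fits a Bayesian logistic
    regression with vague priors on prognostic effects and a
    heterogeneity-sceptical prior on treatment-covariate interactions via a
    Polya-Gamma Gibbs sampler, computes personalised treatment effects over
    a covariate grid, builds simultaneous credible bands from the posterior
    draws, and classifies the covariate space into an exclusive benefiting
    subgroup, a no-benefit region, and an uncertainty region with a joint
    posterior bracketing guarantee. Includes a synthetic-cohort generator
    emulating a large lifestyle-intervention trial in type 2 diabetes so
    the full pipeline is testable without restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    grDevices,
    matrixStats,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
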