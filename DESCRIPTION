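Package: phylopom
Title: Phylogenetic Multi-Species Occupancy Models with Spike-and-Slab
    Pagel's Lambda
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Bayesian multi-species occupancy-detection models in
    which species' responses to environmental covariates are phylogenetically
    correlated through Pagel's lambda transform of a phylogenetic correlation
    matrix. Supports two joint detection likelihoods (mist-net and acoustic
    recorder surveys), a spike-and-slab prior on lambda with Bayes-factor
    evidence summaries, per-iteration resampling over a set of candidate
    phylogenies, maximum-likelihood estimation of Pagel's lambda for
    individual traits, phylogenetic imputation of missing trait values under
    a multivariate Brownian-motion model, detectability-corrected species
    richness with Poisson regressions on environmental gradients, and a
    synthetic-community generator for simulation-based validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
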