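Package: divdrivers
Title: Identifying Drivers of Diversification from Phylogenies and Trait Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking and confirming drivers of lineage
    diversification. Implements tip speciation-rate estimation (the DR
    inverse equal-splits statistic), a bootstrapped gradient-boosting
    importance-ranking protocol with quantile significance calls and a
    stump-model interaction contrast, and quantitative-trait
    state-dependent speciation-extinction (QuaSSE-type) likelihoods
    computed by FFT-based reaction-diffusion propagation on a trait grid,
    with maximum-likelihood fitting and AIC model comparison across
    constant, linear, sigmoid and modal speciation functions with and
    without directional trait drift. Includes a forward trait-dependent
    birth-death simulator, synthetic trait-table and occurrence
    generators, and occurrence cleaning, spatial thinning, environmental
    summarisation and area-of-occupancy computation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    mgcv,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
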