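Package: smallarea
Title: Bayesian Small-Area Risk Mapping with Structured Spatial Random Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Poisson hierarchical regression models for small-area count
    data with an intrinsic conditional autoregressive (ICAR) spatial random
    effect and an exchangeable heterogeneity random effect (the
    Besag-York-Mollie convolution model), using a purpose-built adaptive
    Metropolis-within-Gibbs sampler. Provides internal standardization of
    expected counts, Gelman-Rubin convergence diagnostics, DIC model
    comparison, a covariate relevance screening workflow, per-area relative
    risk and exceedance probability surfaces, and a calibrated synthetic-data
    generator for areal count data on lattice or user-supplied adjacency
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
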