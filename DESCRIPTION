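Package: hawkesnet
Title: Network Structure and Spike-Train Correlations in Linearly
    Interacting Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the structure of weighted directed neuronal
    networks to the pairwise correlations of their spiking activity under the
    multivariate Hawkes (linear point process) model. Provides seeded
    generators for random, ring, hub and patchy network architectures,
    closed-form equilibrium rates and integrated spike-train covariances, a
    motif (matrix power series) decomposition of correlations into chain and
    common-input contributions, random-matrix bulk-spectrum stability
    diagnostics, discrete-Fourier analytics for distance-dependent
    correlations on rings, and a compiled time-stepped simulator of the point
    process with estimators that confront theory with sampled spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
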