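Package: nanodosim
Title: Track-Structure Nanodosimetry with Interchangeable Cross-Section Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-by-event Monte Carlo simulation of low-energy electron
    transport in liquid water driven by pluggable total interaction
    cross-section datasets, with scoring of ionization cluster size
    distributions (ICSDs) in nanometric spheres.  Provides tools to read,
    validate, interpolate and average cross-section tables on a standard
    template; to generate synthetic dataset families emulating inter-code
    spread; to compute nanodosimetric quantities (cluster-size moments and
    cumulative probabilities) with GUM-style uncertainties; and to quantify
    inter-dataset variability of ICSDs with the discrete Wasserstein-1
    (earth-mover) distance, including a harmonization experiment that
    contrasts per-dataset simulations with simulations under a common
    (channel-wise averaged) dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
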