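Package: upstates
Title: Spiking-Network Simulation and Analysis of Cortical UP/DOWN State Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates randomly connected networks of adaptive exponential
    integrate-and-fire (AdEx) neurons with spike-frequency adaptation, five
    receptor-mediated synaptic currents (AMPA, NMDA, fast and slow GABA-A,
    GABA-B) with second-order gating kinetics, and connection weights drawn
    from log-normal, sparse-Gaussian or sparse-log-normal ensembles with unit
    mean and tunable variance. Provides a mean-field fixed-point analysis of
    the existence and stability of depolarized UP states, segmentation of
    membrane traces into UP and DOWN states with cycle-duration and Fano-factor
    statistics, and extraction of recurring cell assemblies by non-negative
    matrix factorization with AICc order selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
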