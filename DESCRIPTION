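Package: hdctme
Title: Hybrid Discrete-Continuous Simulation of Early Tumor-Macrophage Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lattice-based hybrid discrete-continuous (HDC) agent-based model of
    the early tumor microenvironment. Tumor cells and macrophages occupy a
    two-dimensional lattice and interact through four diffusible signals
    (a pro-M2 factor, a tumor lethality signal, an activator, and oxygen) and a
    dynamic vasculature layer. The package provides the simulation engine with
    seeded, reproducible stochastic runs; outcome classification into tumor
    survival versus tumor death; the macrophage polarization index and spatial
    heterogeneity metrics; one- and two-parameter multiparametric sensitivity
    analysis with quadratic response-surface sensitivities; and in-silico
    evaluation of engineered-macrophage therapy strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
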