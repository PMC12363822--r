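Package: remapsim
Title: Simulation and Analysis of Place-Cell Remapping with Linear Decoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates hippocampal place-cell remapping in an autoencoder
    network with a linear decoder. Environmental variables (position and
    cognitive) are mapped through an angular latent space, optionally through
    multiple grid modules, into an embedding space, and steady-state
    nonnegative firing rates are obtained by solving a convex quadratic
    program per position. Five remapping scenarios are provided
    (low- and full-dimensional multi-chart, grid-module realignment,
    space-feature and implicit-space mixed selectivity, and null-space
    threshold modulation), together with rate-map overlap and spatial
    correlation statistics tested against shuffle controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'latent-coding.R'
    'cognitive.R'
    'embedding.R'
    'network.R'
    'experiments.R'
    'analysis.R'
    'viz.R'
    'io.R'
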