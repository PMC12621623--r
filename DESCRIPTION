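Package: setascale
Title: Concurrent Multiscale MD-FEM Simulation of Gecko Seta Adhesion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and runs a concurrent multiscale model of a gecko seta
    adhering to a smooth substrate. The micrometer-scale branched setal shaft
    is described by static linear-elastic tetrahedral finite elements, while
    each nanoscale spatula is a coarse-grained bead-spring network undergoing
    thermostatted molecular dynamics against a frozen Lennard-Jones substrate.
    The two descriptions are coupled through per-spatula bridging domains in
    which anchor points (virtual particles at finite element nodes) exchange
    time-averaged forces and displacements with molecular beads via harmonic
    springs. Includes the preload-relax-pull-off loading protocol, a
    constant-velocity shear protocol, and analyses of force, contact, and
    displacement profiles, detachment order, sliding velocity, and apparent
    friction coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
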