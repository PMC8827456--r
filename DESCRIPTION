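Package: thrombosim
Title: Multiscale Stochastic Simulation of Thrombus Growth Under Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional multiscale simulation of platelet deposition and
    thrombus growth under flow at single-platelet resolution. Couples a D3Q19
    lattice Boltzmann solver for blood flow over the evolving platelet mass, a
    rejection-free lattice kinetic Monte Carlo engine for platelet motion and
    bonding, finite-volume convection-diffusion-reaction transport of the
    soluble agonists ADP and thromboxane A2, a pluggable intracellular calcium
    signaling model driving shear-dependent adhesion kinetics (including von
    Willebrand factor capture enhancement at pathological shear rates), and a
    thin-film reduced coagulation cascade producing wall tissue-factor-driven
    thrombin. Ships channel, tube, and stenosis geometries with scenario
    presets for antiplatelet drug treatments and stenosis-severity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
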