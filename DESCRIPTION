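Package: spinepattern
Title: Reaction-Diffusion Simulation and Morphometry of Dendritic Spine Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of neuron dendritic spines with an
    activator-inhibitor-substrate reaction-diffusion model of the
    Gierer-Meinhardt family, extended with exogenous activator and inhibitor
    source terms. Provides explicit finite-difference integration on 2-D
    grids with zero-flux boundaries, single-spine and two-stage dendrite
    simulation protocols, silhouette morphometry with relative average width
    (RAW) and relative constriction width (RCW) metrics for classifying
    spines into mushroom, stubby, thin and branched types, spine density
    measurement along a dendrite trunk, linear stability (Turing) analysis
    of the decoupled activator-inhibitor subsystem including dispersion
    relations and Turing wavelengths, and scripted parameter sweeps
    reproducing the shape- and density-regulation experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
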