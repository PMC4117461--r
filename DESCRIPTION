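Package: sigfluct
Title: Fluctuation Kinetics of Cofactor-Driven Cell Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and stability analysis of a two-variable fluctuation
    kinetic model of cell signaling in which a diffusion-limited signaling
    protein is switched between an interaction-active and an inactive state by
    cofactor (ATP/GTP) binding and hydrolysis. Provides the polynomial
    fluctuation vector field and its steady state, stiff adaptive integration
    of long trajectories, peak-based oscillation metrics (amplitude,
    frequency, sustained/decaying classification), location of the critical
    cofactor supply level both from the linearization and from simulation,
    log-scaling fits of oscillation metrics against the distance above
    criticality, and an eigenvector-coordinate reduction of the dynamics at
    criticality (adiabatic elimination of the fast mode) with root-structure
    and bifurcation analysis of the reduced one-dimensional equation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
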