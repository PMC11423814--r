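Package: mechanoclock
Title: Coupled Mechanotransduction and Circadian Clock Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the coupling between cellular mechanotransduction and the
    mammalian circadian clock. Steady-state nuclear YAP/TAZ and MRTF
    concentrations are computed from mechanical and pharmacological conditions
    (substrate stiffness, contact area, cell density, cytoskeletal inhibitors,
    YAP or lamin A mutations) via an algebraic solution of a reduced
    mechanotransduction network, and drive expression terms of a three-species
    delay-differential-equation clock (BMAL1, PER/CRY, REV-ERBalpha) with a
    luciferase reporter. Includes a method-of-steps DDE integrator,
    population-variability simulation with log-normal and posterior parameter
    sampling, a spectral circadian power-fraction statistic, Bayesian
    calibration with an affine-invariant ensemble sampler, total-order Sobol'
    sensitivity indices, and Hopf-bifurcation analysis of the linearized delay
    system.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
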