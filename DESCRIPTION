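Package: notchsim
Title: Simulation and Bifurcation Analysis of DLL4/JAG1-Notch-VEGF
    Signalling with Ligand Heterodimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic models of Notch lateral inhibition in
    angiogenesis in which the ligands DLL4 and JAG1 compete through
    heterodimer formation. Provides mass-action ODE right-hand sides for a
    ligand-competition model and its extension with VEGF-VEGFR2 feedback,
    a fixed-step Runge-Kutta integrator with species clamping, closed-form
    steady-state analysis of the ligand cubic equations, two-cell
    equilibrium and bifurcation machinery (multistart Newton, Jacobian
    stability, natural-parameter continuation, patterning phase diagrams),
    hexagonal-lattice tissue simulations under an exponential VEGF
    gradient with tip/stalk classification, and a scenario registry with a
    command-line interface that reproduces the in-silico experiments.
    All results are returned as tibbles with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
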