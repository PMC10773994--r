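Package: gravitroot
Title: Root Gravitropism Dynamics with Apical Sensing and a Finite Growth
    Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation, inference and analysis tools for the tropic
    dynamics of plant roots. Implements a growth-driven model of root
    gravitropism in which gravity is sensed apically (at the root cap)
    while curvature is produced in a finite subapical growth zone, so the
    shape laid down during the response is progressively frozen into the
    mature zone. Provides the reduced nondimensional ODE for the
    growth-zone curvature, a Lagrangian material-point solver for the
    underlying transport equation, comparison models without growth and
    with whole-organ exponential growth, a damped-harmonic-oscillator
    reduction, nonlinear least-squares estimation of gravitropic and
    proprioceptive sensitivities from tip-angle trajectories, curvature
    kymograph analysis (growth-zone length estimation, time to
    equilibrium, shape comparison scores), and a synthetic-cohort
    generator emulating horizontal gravistimulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
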