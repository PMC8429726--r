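Package: chemosched
Title: Robust Chemotherapy Dose Scheduling via Reinforcement Learning and
    Discrete Optimal Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and stress-testing daily chemotherapy dosing
    schedules on a two-compartment proliferative/quiescent cell-population
    model. Provides exact matrix-exponential simulation of the tumour and
    bone-marrow dynamics, closed-form steady-state initial conditions, local
    sensitivity analysis, Latin hypercube virtual-patient cohort generation,
    an exact dynamic-programming solver for the discrete-dose finite-horizon
    optimal control problem, a deep double Q-learning dosing agent trained on
    the nominal patient only, a nearest-training-neighbour optimal controller,
    and evaluation statistics (scaled scores, signed-rank and
    Kolmogorov-Smirnov comparisons) for contrasting controller robustness on
    perturbed virtual patients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
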