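Package: stoclife
Title: Optimal Life Schedules and Linear Demographic Models under
    Internal Stochasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for controlled stochastic life histories and their
    demography. Individual growth follows a controlled Ito diffusion;
    fertility is either a boundary event at maturation (semelparity) or a
    state-dependent rate up to a maximum lifespan (iteroparity). The
    package simulates seeded path ensembles, estimates the expectation of
    reproductive success and its Laplace-transform objective, solves the
    Euler-Lotka equation for the intrinsic rate of increase, marches the
    Fokker-Planck projection kernel, assembles age-size transition
    matrices, and solves stationary and finite-horizon
    Hamilton-Jacobi-Bellman equations for the optimal Markovian control.
    A two-resource utilization application provides closed forms for the
    optimal resource mix, the generalist window, and breeding-age
    structure in both breeding systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    pracma,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'life_history.R'
    'config_io.R'
    'trajectory_sim.R'
    'demography.R'
    'pde_engine.R'
    'hjb_control.R'
    'two_resource.R'
    'workbench.R'
    'stoclife-package.R'
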