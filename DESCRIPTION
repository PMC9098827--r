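Package: genmod
Title: Generalized Modeling of Dynamical Systems with Unspecified Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for generalized modeling (GM) of ordinary differential
    equation systems whose process kinetics are left unspecified. From a
    declared model structure (variables, signed gain/loss processes,
    dependency sets, auxiliary constraints) the package derives the
    normalized generalized Jacobian symbolically, parameterized by
    interpretable scale parameters (turnover rates, branching weights) and
    exponent parameters (elasticities). The Jacobian can then be analyzed by
    ensemble stability sampling and stability correlations, proportion-of-
    stable-webs parameter sweeps, press-perturbation response and
    eigenvector-based sensitivity/influence scores, saddle-node and Hopf
    bifurcation scanning, and realization of explicit conventional models
    (power-law or saturating kinetics) whose steady state reproduces a chosen
    generalized parameter set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    pracma,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
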