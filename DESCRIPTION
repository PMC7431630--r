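Package: spinectrl
Title: Control-Based Finite-Element Estimation of Trunk Muscle Forces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-dynamic estimation of trunk muscle forces in the frontal
    plane.  A geometrically nonlinear corotational beam-column model of the
    lumbar spine is actuated by five pairs of Hill-type muscles whose
    activations are set online by per-muscle adaptive fuzzy neuro-controllers
    that minimise a kinematic-error-plus-activation cost.  Includes a
    follower-load-constrained equilibrium baseline on the same geometry,
    section-load recovery (compression and shear per lumbar level),
    follower-load angle metrics, load sweeps and perturbation protocols,
    with tidy tibble outputs and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
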