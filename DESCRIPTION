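Package: pursuitglm
Title: Pursuit-Evasion Task Simulation and LN-Poisson Encoding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a continuous joystick pursuit/evasion task (cost-minimizing
    evasive prey, distance-minimizing predator, parameterized subject policies),
    generates ground-truth linear-nonlinear (LN) Poisson ensembles from the
    resulting trajectories, and analyzes them end to end: penalized LN-Poisson
    tuning-model fits with ten-fold cross-validation and forward model selection,
    response profiles, adaptive rate-map smoothing, SPAEF map similarity, effect
    sizes, multiplicative/additive mixed-selectivity statistics, maximum-likelihood
    population decoding, and behavioral classifiers (trajectory-based trial
    sorting, chase/avoid labeling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
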