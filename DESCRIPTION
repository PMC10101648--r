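Package: motorloop
Title: Basal Ganglia and Cerebellum Interactions in Motor Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systems-level simulation of motor learning in a cortex-basal
    ganglia motor loop coupled to a reservoir-computing cerebellum, both
    setting the parameters of brainstem central pattern generators (CPGs)
    that drive a four-degree-of-freedom arm. The basal ganglia select
    discrete "concrete actions" (full CPG parameter sets) through a
    direct-pathway rate model trained by novelty-gated dopamine-modulated
    Hebbian plasticity; the cerebellum fine-tunes the selected parameters
    through node-perturbation reservoir learning driven by the aiming
    error. Includes the reaching and visuomotor-rotation adaptation
    protocols (rotation, strategy, and rotation-plus-strategy conditions),
    cerebellum-only and no-cerebellum ablations, and motor-variability
    sweeps, with tidy trial logs, broom-style tidiers and ggplot2 plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
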