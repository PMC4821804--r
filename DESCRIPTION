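Package: conflearn
Title: Confidence-Guided Reinforcement Learning for Perceptual Learning
    Without External Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling perceptual learning in the absence of
    external feedback, where confidence acts as an internally generated
    reinforcement signal.  Provides Gabor-in-noise stimulus synthesis,
    a quadrature-filter orientation-energy front end, a trial-by-trial
    associative reinforcement-learning model driven by confidence
    prediction errors, weighted up-down adaptive staircases, two-stage
    maximum-likelihood model fitting, a synthetic-observer experiment
    generator, and desk-scale analyses (confidence calibration curves,
    weight trajectories, perceptual learning indices, and simulated
    BOLD time courses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
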