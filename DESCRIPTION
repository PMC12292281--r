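Package: woundloop
Title: Closed-Loop Control of Wound Healing with Latent Linear Dynamics and
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@woundloop.dev",
           role = c("aut", "cre"))
Description: Tools for simulating and controlling the four-stage wound-healing
    process (hemostasis, inflammation, proliferation, maturation). Provides a
    linear compartmental stage model on the probability simplex with
    discrete-time LQR reference control, a synthetic wound-image simulator with
    a treatment-effect model for electric-field and fluoxetine actuation, an
    autoencoder ("mapper") that links wound images to the linear stage space
    while learning its rate constants, an advantage actor-critic agent that
    tracks LQR-generated reference states, and the closed-loop orchestration
    including treatment-modality switching and iontophoretic dose accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
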