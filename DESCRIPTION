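Package: calfads
Title: Latent Factor Analysis via Dynamical Systems for Calcium
    Fluorescence Population Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a causal sequential variational autoencoder (an LFADS
    variant with Gaussian emissions) to trial-structured calcium
    fluorescence population recordings, and reverse-engineers the learned
    generator dynamics.  Includes a ground-truth attractor simulator for
    validation, fixed-point analysis with Jacobian linearization and
    line/point attractor classification, targeted dimensionality
    reduction onto total-activity / condition-independent /
    line-attractor modes, in silico reward-probability titration of the
    trained generator, session-level statistics (task modulation,
    post-perturbation recovery time, ramping classification, hierarchical
    bootstrap, integration tests), and fiber-photometry preprocessing
    with isosbestic control correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
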