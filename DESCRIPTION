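Package: saccsim
Title: Closed-Loop Optimal Control Simulation of Saccadic Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates saccadic and smooth-pursuit eye movements with a
    finite-horizon linear-quadratic controller coupled to an adaptive Kalman
    estimator that extrapolates delayed retinal feedback through the stored
    motor-command history. Because motor noise is signal-dependent, the
    variance of the extrapolated feedback rises around saccades and the
    Kalman weight given to sensory input drops: the package derives this
    perisaccadic suppression window, its scaling with saccade amplitude, and
    the contrast between catch-up saccades and smooth pursuit initiation from
    simulated trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
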