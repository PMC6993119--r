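Package: kneeload
Title: Knee Joint Moment Estimation from Two Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates stance-phase external knee flexion and adduction
    moment time series from two leg-worn six-channel inertial measurement
    units using a feed-forward neural network trained with
    Levenberg-Marquardt optimization. Provides a seeded synthetic gait
    cohort simulator, plain-text trial and model formats, signal
    preprocessing (zero-phase low-pass filtering, vertical ground reaction
    force stance detection, stance-phase time normalization, body-mass
    moment normalization), Nguyen-Widrow network initialization, an
    analytic-Jacobian Levenberg-Marquardt trainer, and a
    leave-one-subject-out cross-validation harness with continuous
    agreement metrics (Pearson r with Fisher-z pooling, RMSE, relative
    RMSE) and discrete knee-load metrics (peak, impulse, percent
    difference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
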