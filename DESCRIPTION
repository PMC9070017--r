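Package: rsvpalpha
Title: Target-Related Alpha Attenuation and Classification in RSVP
    Brain-Computer Interface Calibrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for rapid serial visual
    presentation (RSVP) electroencephalography calibrations used by
    event-related-potential spellers.  Provides a synthetic multichannel
    EEG generator with posterior-dominant alpha, target-locked alpha
    attenuation (event-related desynchronization), N200/P300 templates,
    steady-state visual-evoked-potential harmonics, 1/f background noise
    and blink artifacts; zero-phase Butterworth filtering, resampling,
    channel pooling and stimulus-locked epoching; threshold-based
    artifact flagging; epoch-averaged amplitude spectra with individual
    alpha frequency estimation; complex Morlet continuous wavelet
    scaleograms with baseline Z-transformation and alpha-attenuation
    measurement; ERP peak detection and target effects; nonparametric
    statistics; and target/non-target classifiers (L2 logistic
    regression, support vector, Riemannian tangent space, uniform-random
    control, and an RDA/KDE ERP reference) evaluated by balanced
    accuracy with baseline/response window tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
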