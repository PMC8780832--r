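Package: adlsphere
Title: Visualization-Driven Analysis of Multi-Day Waist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-day 100 Hz waist-worn inertial sensor
    recordings of activities of daily living. Acceleration samples are mapped to
    spherical coordinates and projected onto the unit acceleration sphere, where
    a 1-degree orientation grid summarises per-bin probability, mean and
    variability of the acceleration magnitude. Bin-level filters combined with
    elevation and daytime constraints extract information-rich 3-second windows
    for sequence classification with a from-scratch LSTM network. Scalar
    movement metrics relevant to post-stroke movement asymmetry are included:
    the higher-acceleration fraction, the acceleration asymmetry index,
    actigraphic sleep detection, banded activity amplitudes, movement-transition
    statistics and complex Morlet wavelet spectrograms. A seeded synthetic
    generator of healthy-like and stroke-like recordings makes the whole
    pipeline testable without raw sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
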