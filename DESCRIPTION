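Package: harpool
Title: Redundancy-Aware Pooling and Histogram Encoding for Accelerometer-Based Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying pooling operators in human activity recognition
    (HAR) from tri-axial accelerometer streams. Implements two bounded pooling
    reducers - extrema contrast pooling (ECP) and center-minus-variation (CMV) -
    alongside classical max and average pooling, a histogram-to-RGB encoder that
    turns signal windows into small images, reference 1D and 2D convolutional
    network classifiers with pluggable pooling layers, a seeded noise-injection
    suite (Gaussian, salt-and-pepper, speckle, mixture, baseline drift, motion
    artifacts), and a signal-deviation robustness benchmark. A synthetic
    generator emulates the WISDM accelerometer CSV format (user, activity,
    timestamp, x, y, z at a nominal 20 Hz) with six activity classes so the
    full pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
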