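Package: subtremor
Title: Subclinical Tremor Differentiation from Wearable Orientation Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for differentiating subclinical rest tremor
    of Parkinson's disease, essential tremor and healthy physiological tremor
    from quaternion orientation streams recorded by three arm-mounted inertial
    sensors. Converts orientations to reference-point displacement signals,
    gates recordings by a joint-angle tremor-rating regression (subclinical
    defined as rating below 0.5), repairs transmission gaps by piecewise cubic
    Hermite interpolation, band-passes to the 3-30 Hz tremor band, extracts
    short-time Fourier magnitude sequences and classifies them with a long
    short-term memory (LSTM) network trained with Adam, early stopping,
    stratified 5-fold cross-validation and time-slice oversampling. Includes a
    seeded synthetic tremor simulator so every stage can be exercised without
    clinical data, a convolutional-LSTM reference architecture, and a full
    one-vs-all confusion/ROC evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
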