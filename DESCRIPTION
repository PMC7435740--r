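Package: dopplerfhr
Title: Beat-to-Beat Fetal Heart Rate Extraction from Doppler Ultrasound Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete processing channel that turns a raw demodulated fetal
    Doppler ultrasound signal into a beat-to-beat fetal heart rate signal in the
    form of a time series of events. Implements band separation of heart-wall and
    valve components, envelope detection (rectify/low-pass and Hilbert), windowed
    autocorrelation periodicity measurement with a trapezoidal prediction
    function, two event-extraction methods (duplicate-measurement correction of a
    250-ms series, and median segmentation of 25-ms instantaneous measurements
    with a matching correction), artifact validation, and an evaluation
    methodology (event-series synchronization, interval-error statistics, signal
    loss, and twelve short/long-term variability indices). A synthetic Doppler
    signal simulator with known beat times makes every stage testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
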