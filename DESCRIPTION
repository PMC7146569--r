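Package: tdhr
Title: Time-Domain Heart-Rate Estimation from Wrist Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-domain heart-rate estimation from wrist photoplethysmography
    (PPG) designed for low-resource wearable devices. Implements two-stage
    band-pass signal conditioning with a nonlinear output limiter for fast
    recovery from motion transients, a memory-reduced binary variant of the
    automatic multiscale peak detection (AMPD) algorithm with a noise-quality
    gate, accelerometer-based exclusion of movement-corrupted inter-beat
    periods, and median inter-beat heart-rate estimation over sliding windows.
    Includes a synthetic PPG and accelerometer recording generator with known
    ground truth, and an evaluation harness reporting mean absolute error and
    valid-measurement fraction against a reference heart-rate series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
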