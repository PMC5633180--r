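Package: wardsense
Title: Bed and Chair Exit Detection from Battery-Less RFID Wearable Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Movement-monitoring pipeline for recognizing bed and chair exits of
    hospitalized older people from sparse, irregular sensor streams backscattered
    by a battery-less RFID wearable accelerometer. Implements canonical stream
    I/O and validation, instantaneous and 4-second contextual feature extraction
    (trunk angles, RSSI and RF-phase rate summaries, bed-chair antenna mutual
    information), class-weighted one-vs-one support vector machine activity
    classification with evolutionary (CMA-ES) class-weight search, windowed
    score-function smoothing with a posture-transition state machine and 1.75 s
    alarm refractory period, tolerance-based event-level evaluation with
    patient-level leave-one-out cross-validation, and a synthetic ward simulator
    with three-antenna RSSI/phase physics and class-dependent read sparsity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
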