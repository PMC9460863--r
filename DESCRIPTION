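Package: emoglove
Title: Emotion Recognition from Physiological Signals and a Data-Glove Wire Protocol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for valence-arousal emotion recognition from skin-electrical
    (galvanic skin response) and pulse-wave (photoplethysmogram) signals, and for
    the binary wire protocol of a sensing data glove. Includes seeded synthetic
    generators for emotion-conditioned physiological traces and glove byte
    streams; wavelet denoising, zero-phase Butterworth filtering, min-max
    normalization and windowed segmentation; pulse-wave beat detection with
    fiducial-point location (systolic peak, dicrotic notch, dicrotic wave) and
    the BpNN50 beat-interval statistic; skin-electrical range, first-difference
    mean and trend-direction features; PCA-based feature selection with Pearson
    correlation screening and threshold calibration; a rule-cascade quadrant
    judge (HANV, LANV, HAPV, LAPV); finger-bending and IMU frame codecs with
    byte-sum checksums and stream resynchronization; and an interaction layer
    mapping emotions to gesture and steering commands with a timing-deviation
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
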