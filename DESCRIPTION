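Package: pulsespec
Title: Harmonic Pulse-Spectrum Analysis and Classification of Arterial Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-domain analysis of continuous arterial
    pulse recordings (radial blood-pressure waveforms and finger
    photoplethysmography). Removes baseline drift with a high-order
    Chebyshev high-pass filter, detects beat onsets (foot points),
    computes per-beat Fourier harmonic amplitude proportions and phase
    angles, derives sliding-window variability indices, and runs a
    subject-level multilayer-perceptron classification protocol with
    cross-validation and hold-out evaluation, plus per-index two-group
    comparisons. Includes a phenomenological synthetic-waveform
    generator with ground-truth annotations so the whole pipeline is
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC,
    withr
Config/testthat/edition: 3
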