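Package: gazecal
Title: Adaptive Eye-Tracker Calibration and Validation with a Synthetic
    Gaze Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hardware-free implementation of an adaptive, controller-driven
    calibration and validation workflow for screen-based eye trackers.
    Provides a calibration/validation session state machine with a
    programmable controller contract, an automated gaze-contingent
    calibration procedure designed for participants who cannot follow
    instructions (such as nonhuman primates), standardized data-quality
    metrics (accuracy, RMS sample-to-sample precision, STD precision, data
    loss), a per-eye raw-to-screen calibration model, and a synthetic
    binocular gaze simulator with known ground truth so the entire
    procedure can be exercised and tested end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
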