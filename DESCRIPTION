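Package: omrkit
Title: Automated Optomotor-Response Measurement for Freely Moving Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure mouse visual performance from optomotor responses
    (OMR) without head fixation or markers. Provides markerless head-gaze
    tracking from overhead video frames (threshold calibration, segmentation,
    weighted center of gravity, nose and head localization), virtual-cylinder
    grating stimulus geometry with head-position feedback and display
    luminance linearization, and automated quantification of tracking
    behavior: stimulus-related-behavior detection from angular velocities,
    chance-level correction, spatial-frequency response curves, and a robust
    logistic fit yielding a visual-acuity threshold. A synthetic-data module
    renders mouse silhouettes with known pose and simulates gaze traces with
    known tracking epochs so the whole pipeline is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
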