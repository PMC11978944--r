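Package: fusulm
Title: Functional Ultrasound and Ultrasound Localization Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combined transcranial functional ultrasound
    (fUS) and ultrasound localization microscopy (ULM) experiments in the mouse
    brain. Models the timing and geometry of motorized multi-array scans,
    computes power Doppler images from SVD clutter-filtered frame stacks,
    localizes and tracks microbubbles into super-resolved density and speed
    maps, estimates image resolution by Fourier ring correlation, detects
    stimulus-evoked activation with a voxel-wise general linear model
    (baseline, stimulation, delta-CBV and rCBV maps), and aggregates
    functional-response versus flow-speed correlations across acquisitions
    with the Fisher transform and Wilcoxon signed-rank test. Includes a
    ground-truthed synthetic-data generator (hierarchical vascular phantoms,
    microbubble frame stacks with low-rank clutter, stimulus-locked Doppler
    time series) so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
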