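Package: hsdefect
Title: Hyperspectral Defect Detection with Learned Band Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for locating and classifying blood-related surface
    defects on poultry carcasses from hyperspectral imagery. Provides
    ENVI-format cube input/output, black/white reflectance calibration,
    pseudo-color band synthesis, a from-scratch 1-D convolutional spectral
    classifier, a discrete firefly metaheuristic for informative band
    selection driven by that classifier, compact one-stage and two-stage
    object detectors with a spectral-spatial feature-fusion head, a full
    detection metrics suite (IoU, precision/recall/F1, AP, mAP, mIoU,
    confusion matrices), and a synthetic scene generator so every stage is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    png,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
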