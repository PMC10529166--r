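Package: woundmetric
Title: Wound Area Measurement and Tissue Classification from Calibrated Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative wound assessment from mobile photographs:
    scribble-seeded superpixel segmentation of the wound region of interest,
    detection and geometric validation of a blue 2 cm x 2 cm fiducial marker for
    pixel-to-cm2 calibration, physical wound-area measurement (digital
    planimetry), tracing-agreement error metrics (FNR, FPR, RV, Jaccard, Dice,
    intraclass correlation), and patch-based classification of wound tissue into
    necrotic, slough and granulation classes. A synthetic-scene generator
    renders wound photographs with complete ground truth so every stage of the
    pipeline can be tested without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
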