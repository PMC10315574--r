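Package: colonyscreen
Title: Colony Detection, Screening and Robotic Pick-List Generation from
    Petri Dish Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classical image-analysis pipeline for bacterial colony
    screening on agar plates: detects the Petri dish, segments colonies by
    adaptive Gaussian thresholding with convex-hull regularisation, splits
    touching colony groups by local-maximum search and marker-controlled
    watershed, measures size, HSV colour and fluorescence per colony,
    ranks candidates by a user-weighted score, and maps selected colonies
    from image pixels to liquid-handler millimetre coordinates as a
    picklist CSV.  Ships a synthetic plate generator with exhaustive
    ground truth, a COCO-panoptic dataset exporter with 15-fold
    rotation/mirror augmentation, and detection benchmarking metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
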