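Package: hipwear
Title: Hybrid Circle Detection and Prosthesis Wear Measurement for AP Hip Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the femoral head and acetabular cup as circles in
    anteroposterior hip radiographs and quantifies polyethylene wear between
    serial images. Region-of-interest proposals (from an external detector or a
    built-in oracle provider) are refined by radial Edge-Snap alignment,
    RANSAC circle fitting and a circular Hough-transform fallback under
    anatomical plausibility constraints. Wear is reported as medial, superior
    and resultant displacement components with femoral-head-radius scale
    normalization. Includes adaptive Canny edge extraction, detection metrics
    (IoU, precision/recall, average precision), a synthetic phantom generator
    with ground-truth labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
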