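Package: bloodcount
Title: Blood Cell Identification and Counting from Smear-Image Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Post-processing pipeline for automated complete blood cell
    counts from object-detector output on stained smear images. Provides
    Pascal VOC annotation handling (BCCD dialect), per-class confidence
    threshold calibration by mean absolute count error, nearest-neighbour
    plus intersection-over-union duplicate suppression for platelets,
    circular cell markers, grid tiling with coordinate reprojection for
    high-resolution smears, and count/accuracy reporting. Includes a
    synthetic smear generator and a configurable noisy oracle detector so
    the whole pipeline is testable without a trained network.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
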