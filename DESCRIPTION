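Package: epidtrack
Title: In Vivo Tracking-Error QA for Marker-Based Dynamic Tumour Tracking from Portal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance pipeline for gimbal-based dynamic tumour tracking
    (DTT) radiotherapy using electronic portal imaging device (EPID) frames.
    Detects the MLC-defined radiation aperture with a Freeman chain-code boundary
    tracer, locates implanted gold fiducial markers with Laplacian-of-Gaussian
    filtering and connected-neighbour labeling, computes the baseline-referenced
    tracking error per frame in the pan, tilt and 2D directions at the isocenter
    plane, and aggregates per-field, per-patient and population statistics
    (systematic and random errors) into a Van Herk planning-target-margin
    contribution. A synthetic EPID phantom generator with known ground truth makes
    every stage testable without clinical images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
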