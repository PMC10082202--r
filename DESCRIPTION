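Package: filterscan
Title: Whole-Slide Imaging Simulation and Rule-Based Cell Detection for
    Microfilter Captures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates multi-channel, multi-focal-plane fluorescence scans of
    wavy microfilter membranes bearing tumor cells (DAPI+/CK+), cancer
    associated fibroblasts (DAPI+/FAP+), hollow pores and fluorophore
    precipitates, with pixel-exact ground truth; and implements the
    computational chain used to analyse such scans: Tenengrad autofocus with
    Gaussian best-focus estimation, patch-wise all-in-focus fusion of fine
    z-stacks, retrospective flat-field correction, subpixel phase-correlation
    registration and distance-weighted mosaic stitching, a rule-based
    multi-channel cell detector with watershed segmentation and marker logic,
    dot-annotation to bounding-box fusion, whole-slide detection with
    half-shift tile coverage, ensemble fusion and overlap-ratio
    deduplication, and precision-recall evaluation with bootstrap error bars
    and the two-proportion z-test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
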