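Package: ermorph
Title: Endoplasmic Reticulum Morphometry for Yeast High-Content Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies endoplasmic reticulum (ER) morphology in fluorescence
    micrographs of budding yeast and scores genome-scale ER-expansion screens.
    Provides mid-section cell segmentation (FFT bandpass contrast enhancement,
    Frangi vesselness border detection, watershed splitting, minimum-volume
    enclosing-ellipse cell borders) with three peripheral-ER size metrics;
    a cortical-section classifier that separates ER tubules, sheets and
    tubular clusters using ring-kernel feature segmentation and
    trimming-factor morphological opening; and plate-based screen scoring
    with local-regression covariate correction, background-population Z
    scores and two-of-three-metric hit calling. A seeded synthetic-microscopy
    generator renders multi-channel fields with ground-truth masks so every
    stage is testable without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
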