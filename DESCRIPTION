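Package: fascore
Title: Quantification of Retinal Pigment Epithelium Disease Area from
    Early-Phase Fluorescein Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step pipeline for quantifying the retinal pigment
    epithelium (RPE) disease area from pairs or series of early-phase
    fluorescein angiography (FA) images. An abnormal-region mask (predicted
    by a small U-net, loaded from annotation files, or taken from synthetic
    ground truth) filters the image; pairs are aligned by FAST corner
    detection, BRIEF descriptor matching and RANSAC affine estimation; the
    luminance slope is removed by Gaussian background division (sigma = 70
    px) followed by histogram matching; mottled hyperfluorescence is
    binarized at 1.2 times the mode intensity; hyperfluorescent pixels are
    counted inside the merged mask to give per-image Scores and a Growth
    rate. Includes a synthetic fundus generator with full ground truth, a
    pixelwise sensitivity/specificity evaluator, and a Jonckheere-Terpstra
    trend test with exact permutation and tie-corrected normal modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
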