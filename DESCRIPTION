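Package: carfind
Title: Label-Free Brightfield Detection and Counting of Surface-Captured CAR T-Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for digital counting of CAR T-cells
    captured on a CD19-functionalized microfluidic sensor surface and imaged
    by label-free brightfield microscopy. Implements a five-stage candidate
    prefilter (local standard-deviation texture filter, zero-mean normalized
    match filter, negative-value thresholding, local-maxima identification,
    and radial segmentation), random-forest object classification into CAR
    T-cell, platelet, red-blood-cell and debris categories, concentration
    calibration by power-law and logarithmic fits with blank-based 95%
    limits of detection and quantification, and a fluorescence-validation
    arm (per-cell SD/median statistic with two-Gaussian mixture gating).
    A ground-truthed synthetic image and calibration generator emulating
    the instrument geometry serves as the test harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
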