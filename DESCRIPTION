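Package: choroidseg
Title: End-to-End Choroidal Segmentation and Morphometry for OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing the choroid in optical coherence tomography
    (OCT) B-scans. Provides multiscale median-cut quantization (MMCQ) vessel
    segmentation with a brightness/contrast perturbation-ensemble majority
    vote, a Niblack local-thresholding baseline, a depth-7 multi-head U-Net
    (implemented natively with RcppArmadillo) that jointly predicts the
    choroidal region, vessels, and fovea location, and derivation of
    fovea-centered choroidal thickness, area, and hard/soft choroidal
    vascularity index on the ETDRS grid. Includes a seeded synthetic B-scan
    generator with exact ground truth, segmentation-agreement statistics
    (Dice, AUC, ICC, Bland-Altman), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
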