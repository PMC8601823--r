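Package: alrls
Title: Adaptive Localizing Region-Based Level Sets with CNN Speed Compensation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of dark air-filled cavities (such as the maxillary
    sinus on CT slices) with localizing region-based level-set active
    contours. Implements the uniform-modeling (Chan-Vese) and mean-separation
    local energies on a narrow band with distance regularization instead of
    reinitialization, and an adaptive speed-compensation scheme in which a
    small convolutional patch classifier inspects contour points that have
    stalled, distinguishes true cavity wall from lesion edges, and injects a
    probability-weighted outward force so the contour escapes local minima
    caused by bright intra-cavity lesions. Includes a synthetic sinus phantom
    generator with ground-truth masks, CLAHE-based patch preprocessing,
    elastic and affine patch augmentation, a pure-R trainable CNN with batch
    normalization and moving-average weights, and an evaluation harness
    (Dice, confidence intervals, initialization-sensitivity experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Segmentation, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
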