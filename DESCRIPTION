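Package: strokesep
Title: Separability Analysis of Subtle Stroke Lesions in CT Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whether acute ischemic lesions that are invisible to
    the eye on non-contrast head CT are nonetheless statistically separable
    from healthy tissue. Provides seeded synthetic head-CT phantoms with
    injectable subtle lesions, two-stage affine registration, brain-midline
    estimation and contralateral mirroring of regions of interest, a
    transform-by-texture radiomic feature bank (first-order, GLCM, GLRLM,
    GLSZM, GLDM, NGTDM over wavelet/intensity/gradient transforms),
    information-gain feature screening, and a repeated stratified k-fold
    cross-validation harness over ten classifier families that reports
    per-threshold and best classification accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    EBImage,
    igraph,
    e1071,
    rpart,
    nnet,
    ranger,
    xgboost,
    class,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
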