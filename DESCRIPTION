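Package: vbmrfe
Title: Coarse-to-Fine Feature Selection and SVM Classification for
    Voxel-Based Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminative analysis of structural-MRI tissue maps with a
    coarse-to-fine feature-selection pipeline: voxelwise pooled two-sample
    t-test screening with cluster-extent filtering, recursive feature
    elimination driven by squared linear support-vector-machine weights, and
    leave-one-out evaluation with proportion-based confusion metrics
    (accuracy, sensitivity, specificity, geometric mean, Dice and F2
    measures) plus ROC/AUC. Includes a seeded synthetic-cohort generator
    producing smoothed tissue-map volumes with planted group differences and
    synthetic atlases, NIfTI input/output, and an atlas-based cluster
    biomarker report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    oro.nifti,
    optparse,
    withr
Config/testthat/edition: 3
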