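Package: segeval
Title: Geometric and Dosimetric Evaluation of Radiotherapy Structure Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation pipeline for candidate organ-at-risk segmentations
    against gold-standard contours in head-and-neck radiotherapy. Provides
    anisotropic voxel-grid geometry (contour rasterization, boundary
    extraction, exact Euclidean distance transforms), the standard geometric
    agreement metrics (volumetric and surface Dice, 95th-percentile Hausdorff
    distance, added path length, contour Dice, voxel confusion rates, volume
    and centroid shifts), dose-volume-histogram statistics with a normalized
    plan-quality metric, missing-structure contingency analysis, the paired
    study statistics used in contouring trials, and a synthetic phantom
    cohort generator with analytically known answers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
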