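Package: micromri
Title: Correlative Microscopy-MRI Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-accurate co-registration of high-resolution microscopy
    volumes to MRI volumes and the quantitative analyses built on top of it:
    landmark-based rigid, similarity, affine and thin-plate-spline
    registration with RMSE evaluation; grouping and downsampling of
    microscopy stacks onto the MRI grid; normal-appearing-gray-matter
    z-normalization and mono-exponential T2* map fitting; paired voxel-table
    extraction with density binning and group statistics; longitudinal
    tumor-growth quantification; vessel local-thickness estimation,
    diameter filtering and equivalence-margin stability checks; kymograph
    line-scan velocimetry; tolerance-aware segmentation evaluation (Dilated
    Dice, mean absolute surface distance) with subject-grouped
    cross-validation splits; and lesion-level cluster quantification.
    A synthetic phantom generator (vessel trees with known radii and flow,
    tumor density fields, sequence-specific MRI contrast, known
    deformations, streaked kymographs) provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
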