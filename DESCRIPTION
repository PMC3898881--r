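Package: longvbm
Title: Longitudinal Voxel-Based Morphometry with Synthetic Phantom Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a longitudinal voxel-based /
    tensor-based morphometry pipeline for serial structural brain images:
    lesion filling, rigid coregistration, non-uniformity correction and brain
    extraction; unbiased within-subject median templates; high-dimensional
    (demons-like) warping with Jacobian-determinant maps; template tissue
    segmentation and "pseudo-time-point" probabilistic grey-matter volumes;
    group-space normalisation without modulation, 8 mm smoothing and an
    explicit grey-matter mask; a two-level summary-statistic model (voxel-wise
    slopes and quadratic terms); permutation inference with threshold-free
    cluster enhancement and family-wise-error correction; and clinical
    association statistics (EDSS steps, MSFC slopes, Box-Cox transforms,
    partial correlations). A synthetic longitudinal phantom generator with
    analytically known regional atrophy provides ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
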