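Package: plantcloud
Title: Down-Sampling Strategies and Segmentation Metrics for Plant
    Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing and evaluating 3D plant phenotyping point
    clouds for point-level deep segmentation networks. Implements five
    down-sampling strategies (farthest point sampling, sequential random
    sampling, two voxel-based samplers, and edge-preserving sampling with a
    surface-boundary filter), per-class semantic segmentation metrics
    (precision, recall, F1, IoU), instance segmentation metrics (mCov,
    mWCov, mPrec, mRec with IoU > 0.5 matching), a rank-based scoring
    harness for comparing strategies across metric tables, a synthetic
    labeled plant generator for dicot- and monocot-like morphologies, and
    readers/writers for labeled-XYZ text, PLY, and HDF5 batch formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RANN,
    rhdf5,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
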