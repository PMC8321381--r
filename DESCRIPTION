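Package: gramfall
Title: Skeleton-Based Fall Detection via Gram-Matrix Trajectories and
    Dynamic Time Warping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies 2D skeleton keypoint sequences as fall or non-fall
    events. Each frame's n x 2 joint configuration is embedded as an n x n
    Gram matrix on the manifold of rank-2 positive semidefinite matrices;
    frames are compared with the Bures/Procrustes Riemannian distance,
    sequences are aligned with Dynamic Time Warping, and sequence-level
    distances are turned into Gaussian-kernel similarity scores that feed a
    linear support vector machine over similarity-score feature vectors.
    Includes readers for CSV and JSON keypoint dumps, a seeded kinematic
    simulator of fall and daily-activity skeleton motion, leave-one-out and
    cross-dataset evaluation protocols, and ROC/confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
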