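Package: forestconn
Title: Random-Forest Segregation of Pharmacological fMRI Connectivity Profiles
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies subjects into treatment groups from region-of-interest
    (ROI) fMRI time series. Each ROI's multi-voxel series is reduced to a
    low-dimensional time course (PCA, isomap, t-SNE or LLE), all-pairs Pearson
    correlations are Fisher z-transformed into a connectivity feature vector
    with a bijective feature-to-ROI-pair index, and subjects are classified by
    a random forest under leave-one-out cross-validation with a probabilistic
    "unclassified" band. Out-of-bag permutation importance ranks discriminative
    ROI pairs; top-k re-classification runs fully nested inside the
    cross-validation loop, and a mutually-exclusive feature-selection procedure
    supports dose-versus-dose contrasts. A synthetic-data generator plants
    group-dependent connectivity effects so the whole pipeline is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    Rtsne,
    data.table,
    jsonlite,
    yaml,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
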