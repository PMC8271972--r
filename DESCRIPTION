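Package: kinegraph
Title: Joint-Angle Synchronization Networks from Wearable-Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns per-individual, per-movement joint-angle synchronization
    networks from wearable-sensor kinematic time series via smoothness-based
    graph learning with a log-degree barrier, using a pairwise dissimilarity
    that penalizes null and near-constant channels. Provides a set-theoretic
    edge-filtering algebra over the union of all learned networks (group,
    side, movement and individual filters; top-K prevalence; group
    differences), per-series measures and group summary curves, network
    centrality feature vectors, PCA / classical MDS projections, a compact
    1D-convolutional autoencoder embedding for time series, arc-diagram and
    comparison renderings, and a synthetic cohort generator with planted
    ground-truth couplings for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
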