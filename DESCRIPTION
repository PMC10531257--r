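Package: hdmea
Title: High-Density Multielectrode Array Activity, Connectivity and
    Current-Source-Density Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-density multielectrode array
    (HD-MEA) extracellular recordings on a rectangular electrode grid:
    spike detection and burst/network-burst statistics, functional
    connectivity inference from spike trains with graph-theoretic
    characterization (clustering coefficient, path length, node degree,
    sender/receiver/broker roles), local field potential (LFP) event
    detection with double-threshold crossing, energy-based duration
    estimation and area-coincidence cleaning, and two-dimensional
    current source density (CSD) analysis via a 9-point Laplacian with
    Hilbert-envelope region- and time-of-interest selection.  Includes a
    ground-truthed synthetic recording generator so every stage is
    testable without proprietary acquisition software, an HDF5 on-disk
    container, and an end-to-end pipeline runner with reproducible
    seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
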