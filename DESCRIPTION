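Package: synloc
Title: Dual-Color SMLM Synapse Nanodomain, Co-Localization and FRAP Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-color single-molecule localization
    microscopy (dSTORM) of synaptic proteins and for fluorescence recovery
    after photobleaching (FRAP). Reads and filters localization tables
    (precision, photon-count and consecutive-localization filters), segments
    synapse regions from widefield reference images at the full-width
    half-maximum, detects subsynaptic nanodomains by local point density with
    Voronoi-cell boundaries, computes nanodomain topology metrics and a
    coordinate-based co-localization index with nanodomain enrichment, and
    estimates FRAP mobile fractions. Includes a ground-truth-labeled
    synthetic-data generator for two-channel synaptic localization data,
    matched widefield images and FRAP recovery traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
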