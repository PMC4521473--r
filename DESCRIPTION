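Package: orgprofiler
Title: Multi-Parametric Phenotypic Profiling of 3-D Organoid Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An image-based high-content-screening pipeline for 3-D cultured
    microtissues (organoids). Two-channel (filamentous-actin and nuclei)
    multi-section image stacks are segmented per section, focus-filtered,
    linked into 3-D objects by mask overlap, and nuclei are assigned as
    children of their parent organoid. A battery of 294 per-well features is
    extracted, including six formula-defined morphology features (invasion
    inhibition, per-organoid size, total proliferation, cell polarity,
    organoid branching, organoid count), then z-score normalized against
    buffer-control wells. Accumulative random-forest feature selection
    (pairwise treatment-versus-buffer, class-wise bootstrap, frequency
    accumulation with a 5 percent cutoff) identifies robust features, and
    Ward hierarchical clustering with Davies-Bouldin / Calinski-Harabasz
    cluster-count selection defines phenotypic classes with signed class
    signatures and per-treatment dose-label sequences. A seeded synthetic
    microtissue generator provides ground-truthed image stacks and planted
    feature tables so that every stage is testable without screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    mclust,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
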