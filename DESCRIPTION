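Package: atlasforge
Title: Construction and Annotation of Hierarchical Single-Cell Atlases
Version: 0.1.0
Authors@R: person("Atlasforge", "Maintainers", email = "maintainers@atlasforge.dev", role = c("aut", "cre"))
Description: A tested, reusable pipeline for building and annotating
    hierarchical single-cell transcriptomic atlases: classifier-entropy
    batch detection, multiresolution cluster-tree construction and
    marker-based pruning, stratified (van Elteren) marker statistics with
    specificity scoring and automated cluster naming, ISH-voxel brain
    region prediction, k-nearest-neighbour label projection with mapping
    probabilities, rank-biased-overlap mapping of bulk signatures onto
    clusters, immediate-early-gene activation scoring, and cross-modality
    correlation. Ships seeded synthetic-data generators with exported
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
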