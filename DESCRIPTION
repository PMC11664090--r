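Package: spatialmvc
Title: Multi-View Variational Graph Auto-Encoders with Consensus
    Clustering for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies spatial domains in spot-level spatial
    transcriptomics data by training one variational graph auto-encoder
    per neighborhood "view" (radius or k-nearest-neighbor graphs over
    spot coordinates, Spearman or cosine graphs over expression),
    optionally refining each latent space with a deep-embedded-clustering
    self-supervision head, clustering every view's embedding with a
    Gaussian mixture model, and merging the per-view partitions through a
    connectivity-matrix consensus step. Includes a Visium-like synthetic
    tissue generator with layered domains and pseudo-histology tiles, the
    standard preprocessing recipe (gene filtering, library-size
    normalization, log transform, highly-variable-gene selection),
    histology-feature expression augmentation, external clustering
    metrics, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
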