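Package: plsnet
Title: Multi-Omics Association Networks via Sparse Partial Least Squares
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integration of multiple omics data blocks (transcriptomics,
    microbiota, cytokines, metabolomics) measured on overlapping sample
    sets into cross-level association networks. Each block is screened for
    treatment-responsive features with moderated linear-model statistics
    and Benjamini-Hochberg false discovery rate control; every pair of
    blocks is then integrated with sparse partial least squares run in both
    predictor/response orientations, the two correlation matrices are
    combined and pruned with dynamic dual thresholds keeping the top
    fraction of positive and negative weights, and threshold significance
    is assessed against a permutation null model. The resulting bipartite
    networks are merged, filtered by network membership, and summarised
    with topology metrics and connectivity-hub detection. Includes a
    synthetic multi-block data generator with planted cross-block
    correlations for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
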