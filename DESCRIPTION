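Package: dctopo
Title: Differential Correlation Analysis via Correlation Network Topology
Version: 0.9.0
Author: Package Author
Maintainer: Package Author <maintainer@example.org>
Description: Untargeted detection of differentially correlated genes between
    two sample groups by comparing the topology of correlation threshold
    networks. Implements a global-topology algorithm (exclusive connected
    components swept over a grid of Fisher-transformed correlation
    thresholds, with run lengths converted to p-values by Steiger's test), a
    local-topology algorithm (Jaccard-type neighborhood dissimilarity
    averaged over the grid), a subsampling-based false discovery rate
    estimator, a latent-factor simulator of two-condition expression data
    with planted differential-correlation modules, and evaluation utilities
    (cross-validation reproducibility, Welch/Benjamini-Hochberg differential
    expression, average-linkage cluster extraction).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
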