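Package: mstknn
Title: Graph-Based Clustering of Expression Metafeatures with MST-kNN Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters transcriptomic features and pairwise "metafeatures"
    (ratios, sums, differences and products of expression values) with a
    modified minimum-spanning-tree / k-nearest-neighbour (MST-kNN) graph
    partitioning algorithm. Supports Jensen-Shannon-divergence disease
    progression scores, Spearman correlation screening against progression
    markers, cluster homogeneity/separation quality metrics, Monte-Carlo
    permutation estimation of the false discovery rate, progression-marker
    cluster reports, and a synthetic planted-block data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
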