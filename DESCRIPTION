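Package: biniR
Title: Biosynthetic Novelty Index Scoring and Gene Cluster Family Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks bacterial strains by the novelty of their biosynthetic
    gene cluster (BGC) repertoires using the biosynthetic novelty index
    (BiNI), the mean distance of a strain's BGCs to their nearest gene
    cluster family (GCF) centroids. Provides antiSMASH region parsing,
    domain-composition featurization, greedy GCF reference building with
    percentile-calibrated novelty thresholds, BGC similarity networks with
    singleton detection, pan-genome core/accessory/unique partitioning with
    rarefaction and Heaps' law open/closed calls, an assembly-fragmentation
    robustness experiment, and a synthetic-data generator with planted
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
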