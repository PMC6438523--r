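Package: coreclust
Title: Genome-Wide Cluster Analysis with Core Genes, Core Samples and
    Combined-Results Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable workflow for genome-wide heatmap analysis of
    feature-by-sample molecular data. Defines a most variable ('core') gene
    set by measures of spread (variance, median absolute deviation,
    inter-quartile range) with percentile cutoffs, including an integrated
    sum-of-ranks selector for sparse data; estimates the number of sample
    clusters by resampling consensus clustering with CDF/delta-area
    statistics; filters a 'core' sample set by per-cluster silhouette-width
    thresholds; merges cluster results from up to three molecular platforms
    through a binary membership matrix (cluster-of-clusters); tests the
    significance of a gene set in separating labelled sample groups against
    size-matched random gene sets; and emits a replayable provenance ledger
    of every parameter, seed and elapsed time so heatmap results can be
    reproduced exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    mclust,
    jsonlite,
    yaml,
    rlang,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
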