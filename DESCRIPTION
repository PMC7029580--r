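Package: astrostates
Title: Identity-Score Annotation and Reactive Astrocyte State Calling for
    Single-Nucleus RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements an annotation pipeline for droplet single-nucleus
    RNA-seq of human cortex: quality filtering on exonic and mitochondrial
    read fractions, pooled size-factor normalization, per-nucleus marker-list
    identity scores with ambiguity flagging, shared-nearest-neighbour
    pre-clustering with enrichment-based resolution of mixed pre-clusters,
    consensus k-means sub-clustering with silhouette evaluation, AUROC and
    pairwise-t marker discovery with ranked log-fold-change marker lists,
    rank-based gene-set scoring of cluster averages, a rule-based classifier
    of astrocyte reactivity states (Quiescent, 1Q, 2R, 3R) from SLC1A2, MT2A
    and GFAP expression, and differential gene-gene correlation between
    conditions with a permutation null. A negative-binomial cohort simulator
    with planted classes, astrocyte states and doublets makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    scran,
    BiocNeighbors,
    igraph,
    cluster,
    Rtsne,
    matrixStats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, Clustering, GeneExpression,
    Classification
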