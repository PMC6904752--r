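Package: scConsolidate
Title: Cluster Consolidation and Downstream Quantification for Timecourse
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for consolidating provisional single-cell clusters across
    replicates and timepoints by centroid rank correlation, with a discard
    rule for clusters that fail to align, batch-corrected pooling and final
    clustering into cell families. Includes quality-control filtering and
    log normalization of UMI count matrices, PCA embedding, cluster-vs-rest
    marker statistics with FDR adjustment, signature-based identity
    assignment, boolean marker gating of mesenchymal subpopulations,
    hierarchical flow-cytometry gate-tree statistics, Yen entropic image
    thresholding with positive-area quantification, and Hounsfield-unit
    threshold CT volumetry. A seeded synthetic-data generator produces
    ground-truth-labelled count matrices, cytometry event tables, images and
    CT volumes with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
biocViews: SingleCell, Clustering, QualityControl, BatchEffect, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
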