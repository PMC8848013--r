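Package: scGRNimpact
Title: Evaluating the Impact of scRNA-seq Imputation on Gene Regulatory
    Network Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained benchmark pipeline for studying how single-cell
    RNA-seq imputation affects gene regulatory network (GRN) reconstruction.
    Simulates overdispersed single-cell counts with dropout from a known
    TF-driven ground-truth network along pseudotime; selects variable genes
    and significantly varying transcription factors with smooth pseudotime
    fits; provides lightweight imputation operators (k-nearest-neighbour
    aggregation, graph diffusion, empirical-Bayes shrinkage) plus an identity
    baseline and an import path for externally imputed matrices; scores
    candidate TF-to-gene edges with tree-ensemble, gradient-boosting,
    mutual-information and partial-correlation methods; and evaluates top-k
    networks by early precision ratio (EPR), log2 performance ratios, network
    density, Jaccard/ARI structure comparison, correlation-class regression,
    chain versus feed-forward-loop motif classification, and binomial
    downsampling stress tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    ranger,
    xgboost,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, GeneRegulation, NetworkInference, SingleCell, Transcriptomics
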