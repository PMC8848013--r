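#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' Ground-truth regulatory network
#'
#' A directed transcription-factor (TF) to target-gene network used as the
#' evaluation truth for network inference. Every edge is sourced at a TF,
#' self-loops are forbidden and the edge set is duplicate-free.
#'
#' @slot tfs character vector of TF identifiers.
#' @slot genes character vector of all gene identifiers (superset of
#'   \code{tfs}).
#' @slot edges data.frame with columns \code{source} and \code{target}.
#' @slot directed logical scalar; the truth networks produced here are
#'   directed.
#'
#' @seealso [sampleGroundTruth()], [harmonizeNetworks()]
#' @export
setClass("GroundTruthNetwork",
    representation(
        tfs = "character",
        genes = "character",
        edges = "data.frame",
        directed = "logical"
    ),
    prototype(directed = TRUE)
)

setValidity("GroundTruthNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("source", "target") %in% colnames(e)))
        msg <- c(msg, "edges must have 'source' and 'target' columns")
    else {
        if (!all(object@tfs %in% object@genes))
            msg <- c(msg, "tfs must be a subset of genes")
        if (nrow(e) > 0) {
            if (!all(e$source %in% object@tfs))
                msg <- c(msg, "every edge source must be a TF")
            if (!all(e$target %in% object@genes))
                msg <- c(msg, "every edge target must be a known gene")
            if (any(e$source == e$target))
                msg <- c(msg, "self-loops are not allowed")
            if (anyDuplicated(paste(e$source, e$target, sep = "\r")))
                msg <- c(msg, "duplicate edges are not allowed")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Single-cell expression dataset with pseudotime and TF annotation
#'
#' Extends \linkS4class{SingleCellExperiment}. The \code{"counts"} assay holds
#' the raw integer matrix; \code{normalizeCounts()} adds a \code{"logcounts"}
#' assay. Per-gene TF status lives in \code{rowData()$is_tf}; per-cell
#' pseudotime (in [0, 1]) in \code{colData()$pseudotime}. A
#' \code{metadata()$layer_tag} string records the active layer
#' (\code{"raw"}, \code{"normalized"} or \code{"imputed:<method>"}).
#'
#' @seealso [ExpressionDataset()], [simulateCounts()], [normalizeCounts()]
#' @export
setClass("ExpressionDataset", contains = "SingleCellExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"is_tf" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must contain a logical 'is_tf' column")
    if (!"pseudotime" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a numeric 'pseudotime' column")
    else {
        pt <- object$pseudotime
        if (!all(is.finite(pt)))
            msg <- c(msg, "pseudotime must be finite")
    }
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "raw counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic single-cell generator. \code{edgesPerGene} is
#' the mean regulatory in-degree of a gene; \code{effectSize} scales the
#' regulatory weights; \code{dispersion} is the negative-binomial
#' overdispersion (variance = mu + dispersion * mu^2); \code{dropoutStrength}
#' controls mean-dependent excess zeros (0 disables them).
#'
#' @seealso [SimulationConfig()], [sampleGroundTruth()], [simulateCounts()]
#' @export
setClass("SimulationConfig",
    representation(
        nTfs = "integer", nGenes = "integer", nCells = "integer",
        edgesPerGene = "numeric", effectSize = "numeric",
        dispersion = "numeric", dropoutStrength = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nTfs < 1L) msg <- c(msg, "nTfs must be >= 1")
    if (object@nTfs >= object@nGenes)
        msg <- c(msg, "nTfs must be smaller than nGenes")
    if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
    if (object@edgesPerGene <= 0) msg <- c(msg, "edgesPerGene must be > 0")
    if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (object@dropoutStrength < 0)
        msg <- c(msg, "dropoutStrength must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Result of one imputation operator
#'
#' @slot matrix genes x cells numeric matrix, same shape and dimnames as the
#'   input layer.
#' @slot methodTag one of \code{"noimp"}, \code{"knn_aggregate"},
#'   \code{"diffusion"}, \code{"shrinkage"} or \code{"external:<name>"}.
#' @slot parameters named list of the settings used.
#' @export
setClass("ImputationResult",
    representation(
        matrix = "matrix",
        methodTag = "character",
        parameters = "list"
    )
)

setValidity("ImputationResult", function(object) {
    msg <- character()
    if (!all(is.finite(object@matrix)))
        msg <- c(msg, "imputed values must be finite")
    else if (any(object@matrix < 0))
        msg <- c(msg, "imputed values must be >= 0")
    if (length(object@methodTag) != 1L)
        msg <- c(msg, "methodTag must be a single string")
    if (length(msg)) msg else TRUE
})

#' Ranked candidate edge list from one GRN method
#'
#' Scored candidate edges with competition ("min") ranks assigned in
#' descending weight order: tied weights share the smallest rank of the tie
#' group. Undirected methods emit each kept pair as two opposing directed
#' records sharing one rank.
#'
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{weight}, \code{rank}.
#' @slot methodTag,imputationTag provenance labels.
#' @slot directed logical; FALSE for methods whose scores are symmetric.
#' @export
setClass("RankedEdgeList",
    representation(
        edges = "data.frame",
        methodTag = "character",
        imputationTag = "character",
        directed = "logical"
    ),
    prototype(methodTag = NA_character_, imputationTag = NA_character_,
              directed = TRUE)
)

setValidity("RankedEdgeList", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("source", "target", "weight", "rank")
    if (!all(need %in% colnames(e)))
        msg <- c(msg, sprintf("edges must have columns %s",
                              paste(need, collapse = ", ")))
    else if (nrow(e) > 0) {
        if (any(e$source == e$target))
            msg <- c(msg, "self-loops are not allowed")
        if (!isTRUE(all.equal(e$rank,
                              competitionRank(e$weight), tolerance = 0)))
            msg <- c(msg, "ranks must be the competition ranking of weights")
    }
    if (length(msg)) msg else TRUE
})

#' Top-k subnetwork of a ranked edge list
#'
#' All edges whose rank is at most k. Because tied weights share ranks, the
#' number of reported edges (\code{nReported}) can exceed k.
#' @export
setClass("TopKNetwork",
    representation(edges = "data.frame", k = "integer", nReported = "integer")
)

#' TP/FP/FN classification of a top-k network against a reference
#'
#' \code{tp} and \code{fp} partition the top-k edges; \code{fn} are reference
#' edges missing from the top-k. When k equals the number of reference edges,
#' |tp| + |fn| = k.
#' @export
setClass("EdgeClassification",
    representation(
        tp = "data.frame", fp = "data.frame", fn = "data.frame",
        k = "integer", nReported = "integer"
    )
)

#' Evaluation metrics for one model (imputation x GRN method) on one dataset
#'
#' Early precision \code{ep} = |TP| / nReported; \code{epr} = ep / density of
#' the evaluation network; EPR = 1 is the random-predictor level. Log2 ratios
#' compare against the matched unimputed model and are \code{NA} until set.
#' @export
setClass("ModelMetrics",
    representation(
        ep = "numeric", epr = "numeric", density = "numeric",
        log2EprRatio = "numeric", log2DensityRatio = "numeric",
        degree = "integer",
        nTp = "integer", nFp = "integer", nFn = "integer",
        k = "integer", nReported = "integer"
    ),
    prototype(log2EprRatio = NA_real_, log2DensityRatio = NA_real_)
)

#' Gene universe selected for network inference
#'
#' Highly variable genes (ranked by deviance explained of a smooth
#' pseudotime fit) plus significantly varying TFs (Bonferroni-corrected
#' p < alpha); the inference universe is their union and is applied
#' identically to every imputation layer.
#' @export
setClass("GeneSelection",
    representation(
        hvgIds = "character",
        sigTfIds = "character",
        universe = "character",
        tfs = "character",
        nTop = "integer",
        alpha = "numeric",
        stats = "data.frame"
    )
)

setValidity("GeneSelection", function(object) {
    msg <- character()
    if (length(object@hvgIds) > object@nTop)
        msg <- c(msg, "more HVGs than nTop")
    if (!all(object@sigTfIds %in% object@tfs))
        msg <- c(msg, "sigTfIds must be TFs")
    if (!all(object@universe %in% c(object@hvgIds, object@sigTfIds)))
        msg <- c(msg, "universe must be the union of HVGs and significant TFs")
    if (length(msg)) msg else TRUE
})

#' Chain/feed-forward-loop classification of a predicted network
#'
#' Counts follow the chain-motif confusion scheme: TP = chain in both
#' networks; FP = predicted chain that is a feed-forward loop in the
#' reference; FN = predicted loop that is a chain in the reference. Motifs
#' whose backbone (X->Y, Y->Z) is absent from the reference are
#' unclassifiable and excluded from TPR/FDR; zero-denominator rates are NA.
#' @export
setClass("MotifClassification",
    representation(
        motifs = "data.frame",
        nTp = "integer", nFp = "integer", nFn = "integer",
        nUnclassifiable = "integer", nLoopAgree = "integer",
        tpr = "numeric", fdr = "numeric"
    )
)
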