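#' @importFrom SummarizedExperiment assay assay<- assayNames rowData colData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Construct an ExpressionDataset
#'
#' @param counts genes x cells matrix of raw counts (integer-valued).
#' @param tfFlags logical vector, one per gene, TRUE for transcription
#'   factors.
#' @param pseudotime numeric vector in [0, 1], one per cell.
#' @param geneIds,cellIds identifiers; defaults taken from dimnames.
#' @param layerTag layer label, \code{"raw"} for count input.
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' ed <- ExpressionDataset(m, tfFlags = c(TRUE, FALSE, FALSE, FALSE),
#'                         pseudotime = seq(0, 1, length.out = 5))
#' @export
ExpressionDataset <- function(counts, tfFlags, pseudotime,
                              geneIds = rownames(counts),
                              cellIds = colnames(counts),
                              layerTag = "raw") {
    counts <- as.matrix(counts)
    if (is.null(geneIds)) geneIds <- sprintf("g%04d", seq_len(nrow(counts)))
    if (is.null(cellIds)) cellIds <- sprintf("c%04d", seq_len(ncol(counts)))
    dimnames(counts) <- list(geneIds, cellIds)
    stopifnot(length(tfFlags) == nrow(counts),
              length(pseudotime) == ncol(counts))
    assayName <- if (identical(layerTag, "raw")) "counts" else "logcounts"
    assays <- stats::setNames(list(counts), assayName)
    sce <- SingleCellExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(is_tf = as.logical(tfFlags),
                                       row.names = geneIds),
        colData = S4Vectors::DataFrame(pseudotime = as.numeric(pseudotime),
                                       row.names = cellIds)
    )
    out <- methods::as(sce, "ExpressionDataset")
    S4Vectors::metadata(out)$layer_tag <- layerTag
    methods::validObject(out)
    out
}

#' @rdname tfFlags
#' @export
setGeneric("tfFlags", function(x) standardGeneric("tfFlags"))

#' TF annotation of a dataset
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @return named logical vector, TRUE for transcription factors.
#' @export
setMethod("tfFlags", "ExpressionDataset", function(x) {
    stats::setNames(rowData(x)$is_tf, rownames(x))
})

#' @rdname pseudotime
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' Pseudotime of the cells
#'
#' @param x an \linkS4class{ExpressionDataset}.
#' @return named numeric vector in [0, 1].
#' @export
setMethod("pseudotime", "ExpressionDataset", function(x) {
    stats::setNames(colData(x)$pseudotime, colnames(x))
})

#' @rdname layerTag
#' @export
setGeneric("layerTag", function(x) standardGeneric("layerTag"))

#' Active layer tag of a dataset
#' @param x an \linkS4class{ExpressionDataset}.
#' @return character scalar.
#' @export
setMethod("layerTag", "ExpressionDataset", function(x) {
    tag <- S4Vectors::metadata(x)$layer_tag
    if (is.null(tag)) "raw" else tag
})

#' @rdname edges
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' Edge table of a network-like object
#' @param x a \linkS4class{GroundTruthNetwork},
#'   \linkS4class{RankedEdgeList} or \linkS4class{TopKNetwork}.
#' @param ... unused.
#' @return data.frame of edges.
#' @export
setMethod("edges", "GroundTruthNetwork", function(x, ...) x@edges)

#' @rdname edges
#' @export
setMethod("edges", "RankedEdgeList", function(x, ...) x@edges)

#' @rdname edges
#' @export
setMethod("edges", "TopKNetwork", function(x, ...) x@edges)

#' @rdname tfSet
#' @export
setGeneric("tfSet", function(x) standardGeneric("tfSet"))

#' TF identifiers of a ground-truth network
#' @param x a \linkS4class{GroundTruthNetwork}.
#' @return character vector.
#' @export
setMethod("tfSet", "GroundTruthNetwork", function(x) x@tfs)

#' @rdname geneSet
#' @export
setGeneric("geneSet", function(x) standardGeneric("geneSet"))

#' Gene identifiers of a ground-truth network
#' @param x a \linkS4class{GroundTruthNetwork}.
#' @return character vector.
#' @export
setMethod("geneSet", "GroundTruthNetwork", function(x) x@genes)

#' @rdname imputedMatrix
#' @export
setGeneric("imputedMatrix", function(x) standardGeneric("imputedMatrix"))

#' Matrix of an imputation result
#' @param x an \linkS4class{ImputationResult}.
#' @return genes x cells numeric matrix.
#' @export
setMethod("imputedMatrix", "ImputationResult", function(x) x@matrix)

#' @rdname methodTag
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))

#' Method tag of a result object
#' @param x an \linkS4class{ImputationResult} or
#'   \linkS4class{RankedEdgeList}.
#' @return character scalar.
#' @export
setMethod("methodTag", "ImputationResult", function(x) x@methodTag)

#' @rdname methodTag
#' @export
setMethod("methodTag", "RankedEdgeList", function(x) x@methodTag)

#' @rdname selectionUniverse
#' @export
setGeneric("selectionUniverse", function(x) standardGeneric("selectionUniverse"))

#' Gene universe of a selection
#' @param x a \linkS4class{GeneSelection}.
#' @return character vector of gene ids used for inference.
#' @export
setMethod("selectionUniverse", "GeneSelection", function(x) x@universe)

setMethod("show", "GroundTruthNetwork", function(object) {
    cat("GroundTruthNetwork:", length(object@genes), "genes (",
        length(object@tfs), "TFs ),", nrow(object@edges),
        if (object@directed) "directed" else "undirected", "edges\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: %d TFs / %d genes / %d cells\n",
        "  edgesPerGene=%.2f effectSize=%.2f dispersion=%.2f ",
        "dropoutStrength=%.2f seed=%d\n"),
        object@nTfs, object@nGenes, object@nCells, object@edgesPerGene,
        object@effectSize, object@dispersion, object@dropoutStrength,
        object@seed))
})

setMethod("show", "RankedEdgeList", function(object) {
    cat("RankedEdgeList:", nrow(object@edges), "edges | method",
        object@methodTag, "| imputation", object@imputationTag, "|",
        if (object@directed) "directed" else "undirected", "\n")
    if (nrow(object@edges) > 0)
        print(utils::head(object@edges, 5L))
})

setMethod("show", "ImputationResult", function(object) {
    cat("ImputationResult [", object@methodTag, "]:",
        nrow(object@matrix), "genes x", ncol(object@matrix), "cells\n")
})

setMethod("show", "TopKNetwork", function(object) {
    cat("TopKNetwork: k =", object@k, ", reported =", object@nReported,
        "edges\n")
})

setMethod("show", "EdgeClassification", function(object) {
    cat("EdgeClassification: TP =", nrow(object@tp), "FP =",
        nrow(object@fp), "FN =", nrow(object@fn), "( k =", object@k, ")\n")
})

setMethod("show", "ModelMetrics", function(object) {
    cat(sprintf("ModelMetrics: EP = %.4f  EPR = %.3f  density = %.4f\n",
                object@ep, object@epr, object@density))
    if (!is.na(object@log2EprRatio))
        cat(sprintf("  log2 EPR ratio vs unimputed = %.3f\n",
                    object@log2EprRatio))
})

setMethod("show", "GeneSelection", function(object) {
    cat("GeneSelection:", length(object@hvgIds), "HVGs +",
        length(object@sigTfIds), "significant TFs ->",
        length(object@universe), "genes (nTop =", object@nTop,
        ", alpha =", object@alpha, ")\n")
})

setMethod("show", "MotifClassification", function(object) {
    cat("MotifClassification: TP =", object@nTp, "FP =", object@nFp,
        "FN =", object@nFn, "unclassifiable =", object@nUnclassifiable,
        "\n  TPR =", signif(object@tpr, 4), " FDR =", signif(object@fdr, 4),
        "\n")
})
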