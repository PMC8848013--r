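#' Competition ("min") ranking of edge weights
#'
#' Ranks weights in descending order of importance; tied weights share the
#' smallest rank of their tie group, so a rank can be skipped after a tie.
#'
#' @param weights numeric vector of edge weights (larger = more important).
#' @return integer vector of ranks, same length as \code{weights}.
#' @examples
#' competitionRank(c(5, 4, 4, 3))  # 1 2 2 4
#' @export
competitionRank <- function(weights) {
    if (length(weights) == 0L) return(integer(0))
    if (any(is.na(weights))) stop("weights must not contain NA")
    as.integer(rank(-weights, ties.method = "min"))
}

edgeKey <- function(source, target) paste(source, target, sep = "\r")

#' Derive a reproducible per-task seed from a master seed and labels
#'
#' Deterministic, label-sensitive and independent of R's RNG state, so adding
#' a cell to an experiment grid never perturbs the seeds of other cells.
#'
#' @param master integer master seed.
#' @param ... character/numeric labels identifying the task.
#' @return integer seed in [0, 2^31 - 1).
#' @export
deriveSeed <- function(master, ...) {
    labels <- paste(c(master, ...), collapse = "|")
    bytes <- utf8ToInt(labels)
    h <- as.numeric(master) %% 2147483647
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    as.integer(h)
}

newRankedEdgeList <- function(source, target, weight,
                              methodTag = NA_character_,
                              imputationTag = NA_character_,
                              directed = TRUE) {
    keep <- source != target
    source <- source[keep]; target <- target[keep]; weight <- weight[keep]
    ord <- order(-weight, source, target)
    source <- source[ord]; target <- target[ord]; weight <- weight[ord]
    e <- data.frame(source = source, target = target, weight = weight,
                    rank = competitionRank(weight),
                    stringsAsFactors = FALSE)
    rownames(e) <- NULL
    new("RankedEdgeList", edges = e, methodTag = methodTag,
        imputationTag = imputationTag, directed = directed)
}

# expand a symmetric weight matrix (genes x genes, rownames set) over the
# requested pairs into two directed records per kept pair sharing one weight
expandUndirected <- function(pairs, weight) {
    data.frame(
        source = c(pairs$a, pairs$b),
        target = c(pairs$b, pairs$a),
        weight = rep(weight, 2L),
        stringsAsFactors = FALSE
    )
}

#' Construct a RankedEdgeList from scored edges
#'
#' Self-loops are dropped and competition ranks are assigned from the
#' weights in descending order.
#'
#' @param source,target character vectors of gene identifiers.
#' @param weight numeric edge scores (larger = more important).
#' @param methodTag,imputationTag provenance labels.
#' @param directed logical; FALSE marks symmetric scores.
#' @return A \linkS4class{RankedEdgeList}.
#' @examples
#' RankedEdgeList(c("TF1", "TF1"), c("g1", "g2"), c(2, 1))
#' @export
RankedEdgeList <- function(source, target, weight,
                           methodTag = NA_character_,
                           imputationTag = NA_character_,
                           directed = TRUE) {
    newRankedEdgeList(source, target, weight, methodTag = methodTag,
                      imputationTag = imputationTag, directed = directed)
}
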