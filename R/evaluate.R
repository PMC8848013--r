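#' Harmonize a predicted ranking and a reference network
#'
#' Applies the evaluation conventions shared by both networks before any
#' scoring: restrict to the selection's gene universe, expand undirected
#' edges into two opposing directed records, keep only edges going out of
#' TFs, drop self-loops, and collapse duplicate directed records
#' (keeping the better, i.e. smaller, rank on the prediction side). Under
#' the TF filter a bidirectional pair survives as two counted edges only
#' when both endpoints are TFs.
#'
#' @param pred a \linkS4class{RankedEdgeList}.
#' @param ref a \linkS4class{GroundTruthNetwork}.
#' @param selection a \linkS4class{GeneSelection} defining the gene universe
#'   and TF set; may be NULL to use the reference's genes/TFs.
#' @return list with elements \code{pred} (rank-recomputed
#'   \linkS4class{RankedEdgeList}), \code{ref} (filtered edge data.frame),
#'   \code{genes}, \code{tfs}, \code{k} (number of positive edges) and
#'   \code{density} of the harmonized reference.
#' @export
harmonizeNetworks <- function(pred, ref, selection = NULL) {
    if (is.null(selection)) {
        genes <- ref@genes; tfs <- ref@tfs
    } else {
        genes <- selectionUniverse(selection)
        tfs <- intersect(genes, selection@tfs)
    }
    pe <- edges(pred)
    pe <- pe[pe$source %in% genes & pe$target %in% genes, , drop = FALSE]
    pe <- pe[pe$source %in% tfs & pe$source != pe$target, , drop = FALSE]
    # collapse duplicates, keeping the best weight/rank
    if (nrow(pe) > 0) {
        pe <- pe[order(pe$rank), , drop = FALSE]
        pe <- pe[!duplicated(edgeKey(pe$source, pe$target)), , drop = FALSE]
    }
    predH <- newRankedEdgeList(pe$source, pe$target, pe$weight,
                               methodTag = pred@methodTag,
                               imputationTag = pred@imputationTag,
                               directed = TRUE)
    re <- edges(ref)
    if (!ref@directed)
        re <- rbind(re, data.frame(source = re$target, target = re$source))
    re <- re[re$source %in% genes & re$target %in% genes, , drop = FALSE]
    re <- re[re$source %in% tfs & re$source != re$target, , drop = FALSE]
    re <- re[!duplicated(edgeKey(re$source, re$target)), , drop = FALSE]
    rownames(re) <- NULL
    if (nrow(re) == 0L)
        stop("no positive edges after harmonization; EPR undefined")
    dens <- networkDensity(nrow(re), length(genes), length(tfs))
    list(pred = predH, ref = re, genes = genes, tfs = tfs,
         k = nrow(re), density = dens)
}

#' Density of a TF-sourced directed network
#'
#' numEdges / ((numGenes x numTFs) - numTFs): the denominator is the number
#' of possible TF-sourced directed edges excluding self-loops.
#'
#' @param numEdges,numGenes,numTfs counts; \code{numGenes >= numTfs >= 1}.
#' @return density in [0, 1].
#' @examples
#' networkDensity(4, 5, 2)  # 0.5
#' @export
networkDensity <- function(numEdges, numGenes, numTfs) {
    stopifnot(numGenes >= numTfs, numTfs >= 1)
    denom <- numGenes * numTfs - numTfs
    if (denom <= 0) stop("degenerate edge universe (single gene)")
    numEdges / denom
}

#' Top-k network of a ranked edge list
#'
#' Keeps every edge whose competition rank is at most k. Because tied
#' weights share ranks, the number of reported edges may exceed k.
#'
#' @param pred a (harmonized) \linkS4class{RankedEdgeList}.
#' @param k rank cutoff; conventionally the number of positive edges in the
#'   evaluation network.
#' @return A \linkS4class{TopKNetwork}.
#' @export
topK <- function(pred, k) {
    stopifnot(k >= 1)
    e <- edges(pred)
    keep <- e[e$rank <= k, , drop = FALSE]
    rownames(keep) <- NULL
    methods::new("TopKNetwork", edges = keep, k = as.integer(k),
                 nReported = nrow(keep))
}

#' Classify top-k edges against a reference
#'
#' TP = top-k edges present in the reference; FP = top-k edges absent from
#' it; FN = reference edges missing from the top-k.
#'
#' @param topk a \linkS4class{TopKNetwork}.
#' @param refEdges harmonized reference edge data.frame (from
#'   [harmonizeNetworks()]).
#' @return An \linkS4class{EdgeClassification}.
#' @export
classifyEdges <- function(topk, refEdges) {
    te <- edges(topk)
    tKey <- edgeKey(te$source, te$target)
    rKey <- edgeKey(refEdges$source, refEdges$target)
    tp <- te[tKey %in% rKey, , drop = FALSE]
    fp <- te[!tKey %in% rKey, , drop = FALSE]
    fn <- refEdges[!rKey %in% tKey, , drop = FALSE]
    rownames(tp) <- rownames(fp) <- rownames(fn) <- NULL
    methods::new("EdgeClassification", tp = tp, fp = fp, fn = fn,
                 k = topk@k, nReported = topk@nReported)
}

#' Early precision and early precision ratio
#'
#' EP = |TP| / nReported (the number of positively predicted edges in the
#' top-k network, which may exceed k through ties); EPR = EP divided by the
#' density of the evaluation network, so that EPR = 1 is the level of a
#' random predictor on any dataset.
#'
#' @param cls an \linkS4class{EdgeClassification}.
#' @param refDensity density of the harmonized evaluation network.
#' @return A \linkS4class{ModelMetrics} (log2 ratios unset).
#' @export
computeEpr <- function(cls, refDensity) {
    stopifnot(refDensity > 0)
    if (cls@nReported == 0L)
        stop("no reported edges in the top-k network; EP undefined")
    ep <- nrow(cls@tp) / cls@nReported
    methods::new("ModelMetrics",
        ep = ep, epr = ep / refDensity, density = refDensity,
        degree = integer(0),
        nTp = nrow(cls@tp), nFp = nrow(cls@fp), nFn = nrow(cls@fn),
        k = cls@k, nReported = cls@nReported)
}

#' Log2 ratio of two positive metrics
#'
#' log2(imputed / unimputed): 0 means no change, -1 a 50% decline.
#' Antisymmetric under swapping the arguments.
#'
#' @param metricImputed,metricUnimputed positive values.
#' @return log2 ratio.
#' @export
log2Ratio <- function(metricImputed, metricUnimputed) {
    if (any(c(metricImputed, metricUnimputed) <= 0))
        stop("log2 ratio requires positive metrics")
    log2(metricImputed / metricUnimputed)
}

#' Degree distribution of a top-k network
#'
#' Total degree per node: all incoming plus outgoing edges within the
#' network.
#'
#' @param topk a \linkS4class{TopKNetwork}.
#' @param nodes optional node universe (defaults to nodes with edges).
#' @return named integer vector of degrees.
#' @export
degreeDistribution <- function(topk, nodes = NULL) {
    e <- edges(topk)
    ids <- c(e$source, e$target)
    if (is.null(nodes)) nodes <- sort(unique(ids))
    deg <- table(factor(ids, levels = nodes))
    stats::setNames(as.integer(deg), nodes)
}

#' Full evaluation of one ranked edge list against a reference
#'
#' Convenience wrapper: harmonize, cut at the reference's k, classify and
#' compute EP/EPR plus the degree distribution.
#'
#' @param pred a \linkS4class{RankedEdgeList}.
#' @param ref a \linkS4class{GroundTruthNetwork}.
#' @param selection optional \linkS4class{GeneSelection}.
#' @param k rank cutoff; defaults to the number of harmonized positive
#'   edges.
#' @return list with \code{harmonized}, \code{topk}, \code{classification}
#'   and \code{metrics}.
#' @export
evaluateRanking <- function(pred, ref, selection = NULL, k = NULL) {
    h <- harmonizeNetworks(pred, ref, selection)
    if (is.null(k)) k <- h$k
    tk <- topK(h$pred, k)
    cls <- classifyEdges(tk, h$ref)
    mm <- computeEpr(cls, h$density)
    mm@degree <- degreeDistribution(tk, nodes = h$genes)
    list(harmonized = h, topk = tk, classification = cls, metrics = mm)
}
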