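#' Jaccard similarity of two edge sets
#'
#' Overlapping interactions divided by the union of reported interactions.
#' Two empty sets are identical by convention (returns 1 with a warning).
#'
#' @param edgesA,edgesB data.frames with \code{source}/\code{target}
#'   columns, or character vectors of edge keys.
#' @return Jaccard index in [0, 1].
#' @export
jaccardSimilarity <- function(edgesA, edgesB) {
    toKey <- function(x) {
        if (is.data.frame(x)) unique(edgeKey(x$source, x$target))
        else unique(as.character(x))
    }
    a <- toKey(edgesA); b <- toKey(edgesB)
    if (length(a) == 0L && length(b) == 0L) {
        warning("both edge sets empty; Jaccard defined as 1 by convention")
        return(1)
    }
    length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard similarity matrix across models
#'
#' @param edgeSets named list of edge data.frames (one per model, typically
#'   the top-500 interactions of each).
#' @return symmetric matrix of Jaccard indices with unit diagonal.
#' @export
similarityMatrix <- function(edgeSets) {
    n <- length(edgeSets)
    stopifnot(n >= 1L)
    labs <- names(edgeSets)
    if (is.null(labs)) labs <- paste0("model", seq_len(n))
    S <- diag(1, n)
    dimnames(S) <- list(labs, labs)
    if (n > 1L)
        for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
            S[i, j] <- S[j, i] <-
                jaccardSimilarity(edgeSets[[i]], edgeSets[[j]])
        }
    S
}

#' Cluster models by network similarity
#'
#' Agglomerative (average-linkage) clustering on 1 - Jaccard distance, cut
#' into \code{nClusters} groups. The partition is invariant to the order of
#' the models.
#'
#' @param sim symmetric Jaccard similarity matrix.
#' @param nClusters requested number of clusters (<= number of models).
#' @return named integer vector of cluster labels.
#' @export
clusterModels <- function(sim, nClusters) {
    stopifnot(nrow(sim) >= 2L)
    if (nClusters > nrow(sim))
        stop("nClusters exceeds the number of models")
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    stats::cutree(hc, k = nClusters)
}

#' Cluster purity as the adjusted Rand index
#'
#' Chance-corrected agreement between a clustering and an annotation label
#' (pair-counting ARI with expected-index correction).
#'
#' @param labelsFound cluster labels.
#' @param labelsAnnotation annotation labels, same length.
#' @return ARI (1 = identical partitions, ~0 = chance).
#' @export
clusterPurityAri <- function(labelsFound, labelsAnnotation) {
    if (length(labelsFound) != length(labelsAnnotation))
        stop("label vectors must have the same length")
    if (length(labelsFound) < 2L)
        stop("need at least two elements to compare partitions")
    mclust::adjustedRandIndex(labelsFound, labelsAnnotation)
}

#' Variance decomposition of log2 EPR ratios over a factorial grid
#'
#' For every dataset: the variance of the log2 EPR ratios across imputation
#' methods at each fixed GRN method, and across GRN methods at each fixed
#' imputation; the two variance collections (pooled over datasets) are
#' compared by a two-sided Wilcoxon rank-sum test. Additionally a per-
#' dataset two-way ANOVA (sequential sums of squares, factor order GRN then
#' imputation) of the log2 ratios on both factors.
#'
#' @param metrics data.frame with columns \code{dataset},
#'   \code{imputation}, \code{grn_method} and \code{log2_epr_ratio}; the
#'   grid must be complete.
#' @return list with \code{var_grn_fixed}, \code{var_imputation_fixed}
#'   (data.frames), \code{wilcoxon_p}, and \code{anova} (one table per
#'   dataset with columns factor, df, sum_sq, f_value, p_value).
#' @export
varianceByFactor <- function(metrics) {
    need <- c("dataset", "imputation", "grn_method", "log2_epr_ratio")
    stopifnot(all(need %in% colnames(metrics)))
    full <- expand.grid(dataset = unique(metrics$dataset),
                        imputation = unique(metrics$imputation),
                        grn_method = unique(metrics$grn_method),
                        stringsAsFactors = FALSE)
    have <- edgeKey(paste(metrics$dataset, metrics$imputation),
                    metrics$grn_method)
    want <- edgeKey(paste(full$dataset, full$imputation), full$grn_method)
    if (!all(want %in% have)) {
        miss <- full[!want %in% have, , drop = FALSE]
        stop("incomplete grid; missing cells: ",
             paste(apply(miss, 1L, paste, collapse = "/"), collapse = "; "))
    }
    aggVar <- function(byCols) {
        out <- stats::aggregate(metrics$log2_epr_ratio,
                                by = lapply(byCols, function(cn) metrics[[cn]]),
                                FUN = stats::var)
        names(out) <- c(byCols, "variance")
        out
    }
    vGrnFixed <- aggVar(c("dataset", "grn_method"))      # varies imputation
    vImpFixed <- aggVar(c("dataset", "imputation"))      # varies GRN
    wp <- if (all(vGrnFixed$variance == vImpFixed$variance[1]) &&
              all(vImpFixed$variance == vGrnFixed$variance[1])) 1 else
        suppressWarnings(stats::wilcox.test(vGrnFixed$variance,
                                            vImpFixed$variance)$p.value)
    anovas <- lapply(split(metrics, metrics$dataset), function(d) {
        if (length(unique(d$grn_method)) < 2L ||
            length(unique(d$imputation)) < 2L) return(NULL)
        fit <- stats::aov(log2_epr_ratio ~ grn_method + imputation, data = d)
        s <- summary(fit)[[1L]]
        data.frame(factor = trimws(rownames(s)), df = s$Df,
                   sum_sq = s$`Sum Sq`, f_value = s$`F value`,
                   p_value = s$`Pr(>F)`, row.names = NULL)
    })
    list(var_grn_fixed = vGrnFixed, var_imputation_fixed = vImpFixed,
         wilcoxon_p = wp, anova = anovas[!vapply(anovas, is.null, logical(1))])
}

#' Rank shifts of unimputed TP edges after imputation
#'
#' For every TP edge of the unimputed top-k network, its rank in the
#' imputed model's full ranking. Edges that the imputed ranking does not
#' report at all get rank universeSize + 1 and are flagged.
#'
#' @param tpEdges data.frame of TP edges with \code{source}/\code{target}
#'   (and optionally \code{rank}, used as rank_before).
#' @param rankingImputed the imputed model's \linkS4class{RankedEdgeList}
#'   (harmonized to the same universe).
#' @param universeSize size of the candidate edge universe, used for the
#'   missing-edge sentinel rank.
#' @return data.frame with source, target, rank_before, rank_after,
#'   missing_after.
#' @export
rankShift <- function(tpEdges, rankingImputed, universeSize = NULL) {
    ie <- edges(rankingImputed)
    if (is.null(universeSize)) universeSize <- nrow(ie)
    idx <- match(edgeKey(tpEdges$source, tpEdges$target),
                 edgeKey(ie$source, ie$target))
    after <- ie$rank[idx]
    missing <- is.na(after)
    after[missing] <- universeSize + 1L
    data.frame(
        source = tpEdges$source, target = tpEdges$target,
        rank_before = if ("rank" %in% colnames(tpEdges)) tpEdges$rank
                      else NA_integer_,
        rank_after = after, missing_after = missing,
        stringsAsFactors = FALSE)
}

#' Correlation-class regression before vs after imputation
#'
#' For every classified edge (TP, FP, FN), the absolute Pearson correlation
#' of its gene pair in the unimputed and in the imputed expression matrix,
#' and one least-squares regression line of |corr after| on |corr before|
#' per class. Edges with a constant gene in either layer have undefined
#' correlation: they are flagged and excluded from the regressions, as are
#' classes with fewer than two usable edges.
#'
#' @param before,after genes x cells matrices (same genes).
#' @param cls an \linkS4class{EdgeClassification}.
#' @return list with \code{table} (per-edge correlations and class) and
#'   \code{lines} (per-class slope/intercept, NA when degenerate).
#' @export
correlationClassRegression <- function(before, after, cls) {
    blocks <- list(TP = cls@tp, FP = cls@fp, FN = cls@fn)
    rows <- do.call(rbind, lapply(names(blocks), function(cl) {
        b <- blocks[[cl]]
        if (nrow(b) == 0L) return(NULL)
        data.frame(source = b$source, target = b$target, class = cl,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) stop("no classified edges")
    absCor <- function(m, s, t) {
        if (stats::sd(m[s, ]) == 0 || stats::sd(m[t, ]) == 0)
            return(NA_real_)
        abs(stats::cor(m[s, ], m[t, ]))
    }
    rows$cor_before <- mapply(function(s, t) absCor(before, s, t),
                              rows$source, rows$target)
    rows$cor_after <- mapply(function(s, t) absCor(after, s, t),
                             rows$source, rows$target)
    rows$degenerate <- is.na(rows$cor_before) | is.na(rows$cor_after)
    lines <- do.call(rbind, lapply(c("TP", "FP", "FN"), function(cl) {
        d <- rows[rows$class == cl & !rows$degenerate, , drop = FALSE]
        if (nrow(d) < 2L || stats::var(d$cor_before) == 0)
            return(data.frame(class = cl, n = nrow(d),
                              slope = NA_real_, intercept = NA_real_))
        fit <- stats::lm(cor_after ~ cor_before, data = d)
        data.frame(class = cl, n = nrow(d),
                   slope = unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]))
    }))
    list(table = rows, lines = lines)
}
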