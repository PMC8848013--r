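#' @importFrom ranger ranger
NULL

# expression matrix (genes x cells) restricted to a selection universe,
# from an ExpressionDataset+selection or an ImputationResult
.exprForInference <- function(data, selection) {
    m <- if (methods::is(data, "ImputationResult")) imputedMatrix(data)
         else assay(data, "logcounts")
    universe <- selectionUniverse(selection)
    miss <- setdiff(universe, rownames(m))
    if (length(miss))
        stop("selection genes missing from matrix: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    m[universe, , drop = FALSE]
}

.selectionTfs <- function(selection) {
    intersect(selectionUniverse(selection), selection@tfs)
}

#' Random-forest edge importance (tree-ensemble GRN inference)
#'
#' For every target gene in the selection universe, fits a random-forest
#' regression of the target on all TF expressions (the target itself
#' excluded from its predictors) and takes the impurity importance of each
#' TF as the TF -> target edge weight. Importances are divided by the
#' target's variance before pooling across targets, so high-variance targets
#' do not dominate the global ranking. Constant targets contribute zero
#' weights.
#'
#' @param data an \linkS4class{ExpressionDataset} (normalized) or an
#'   \linkS4class{ImputationResult}.
#' @param selection a \linkS4class{GeneSelection}; needs >= 2 TFs.
#' @param nTrees number of trees per target.
#' @param seed integer seed (the forest is deterministic given it).
#' @return A directed \linkS4class{RankedEdgeList}, tag \code{"tree"}.
#' @export
inferTreeImportance <- function(data, selection, nTrees = 100L, seed = 1L) {
    expr <- .exprForInference(data, selection)
    tfs <- .selectionTfs(selection)
    if (length(tfs) < 2L) stop("need at least 2 TFs in the selection")
    X <- t(expr[tfs, , drop = FALSE])
    src <- character(0); tgt <- character(0); wt <- numeric(0)
    for (g in rownames(expr)) {
        preds <- setdiff(tfs, g)
        if (length(preds) < 1L) next
        y <- expr[g, ]
        v <- stats::var(y)
        if (v == 0) {
            imp <- stats::setNames(rep(0, length(preds)), preds)
        } else {
            df <- data.frame(y = y, X[, preds, drop = FALSE],
                             check.names = FALSE)
            fit <- ranger::ranger(
                dependent.variable.name = "y", data = df,
                num.trees = nTrees, importance = "impurity",
                seed = deriveSeed(seed, g), num.threads = 1L,
                verbose = FALSE)
            imp <- pmax(fit$variable.importance, 0) / v
        }
        src <- c(src, preds); tgt <- c(tgt, rep(g, length(preds)))
        wt <- c(wt, unname(imp[preds]))
    }
    newRankedEdgeList(src, tgt, wt, methodTag = "tree", directed = TRUE)
}

#' Gradient-boosted edge importance
#'
#' As [inferTreeImportance()] but with gradient-boosted regression trees:
#' per target, boosted rounds with early stopping on a held-out validation
#' fold; edge weight is the total gain importance of each TF, scaled by the
#' target variance.
#'
#' @param data expression input as in [inferTreeImportance()].
#' @param selection a \linkS4class{GeneSelection}; needs >= 2 TFs.
#' @param learningRate boosting shrinkage (eta).
#' @param nRounds maximum boosting rounds.
#' @param seed integer seed controlling the validation fold and fits.
#' @return A directed \linkS4class{RankedEdgeList}, tag \code{"boost"}.
#' @export
inferBoosted <- function(data, selection, learningRate = 0.1,
                         nRounds = 100L, seed = 1L) {
    expr <- .exprForInference(data, selection)
    tfs <- .selectionTfs(selection)
    if (length(tfs) < 2L) stop("need at least 2 TFs in the selection")
    n <- ncol(expr)
    src <- character(0); tgt <- character(0); wt <- numeric(0)
    for (g in rownames(expr)) {
        preds <- setdiff(tfs, g)
        if (length(preds) < 1L) next
        y <- expr[g, ]
        v <- stats::var(y)
        imp <- stats::setNames(rep(0, length(preds)), preds)
        if (v > 0) {
            set.seed(deriveSeed(seed, g))
            val <- sample(n, max(2L, round(0.2 * n)))
            X <- t(expr[preds, , drop = FALSE])
            dtrain <- xgboost::xgb.DMatrix(X[-val, , drop = FALSE],
                                           label = y[-val])
            dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE],
                                         label = y[val])
            fit <- xgboost::xgb.train(
                params = list(objective = "reg:squarederror",
                              eta = learningRate, max_depth = 3L,
                              nthread = 1L, seed = deriveSeed(seed, g)),
                data = dtrain, nrounds = nRounds,
                evals = list(val = dval),
                early_stopping_rounds = 10L, verbose = 0L)
            gain <- tryCatch(xgboost::xgb.importance(model = fit),
                             error = function(e) NULL)
            if (!is.null(gain) && nrow(gain) > 0)
                imp[gain$Feature] <- gain$Gain * v
        }
        src <- c(src, preds); tgt <- c(tgt, rep(g, length(preds)))
        wt <- c(wt, unname(imp[preds]))
    }
    newRankedEdgeList(src, tgt, wt, methodTag = "boost", directed = TRUE)
}

# mutual information (bits) between two integer bin vectors
.miBits <- function(x, y) {
    tab <- table(x, y)
    n <- sum(tab)
    pxy <- tab / n
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

.binEqualFreq <- function(v, nBins) {
    if (stats::var(v) == 0) return(rep(1L, length(v)))
    qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nBins + 1)))
    if (length(qs) < 3L) return(as.integer(factor(v)))
    cut(v, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

#' Mutual-information inference with per-gene context normalization
#'
#' Discretizes each gene into equal-frequency bins, computes pairwise mutual
#' information (in bits) for every TF-gene pair, and normalizes each pair's
#' MI against the MI distributions of its two genes: the edge weight is the
#' mean of the two z-scores (context normalization, CLR-style). Scores are
#' symmetric, so each kept pair is emitted as two opposing directed records
#' sharing one rank. Constant genes have MI 0 by convention.
#'
#' @param data expression input as in [inferTreeImportance()].
#' @param selection a \linkS4class{GeneSelection}.
#' @param nBins number of equal-frequency bins (>= 2).
#' @return An undirected \linkS4class{RankedEdgeList}, tag \code{"mi"}.
#' @export
inferMiContext <- function(data, selection, nBins = 8L) {
    if (nBins < 2L) stop("nBins must be >= 2")
    expr <- .exprForInference(data, selection)
    tfs <- .selectionTfs(selection)
    genes <- rownames(expr)
    bins <- lapply(genes, function(g) .binEqualFreq(expr[g, ], nBins))
    names(bins) <- genes
    pairs <- expand.grid(a = tfs, b = genes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    # keep one record per unordered pair
    swap <- pairs$b %in% tfs & pairs$b < pairs$a
    tmp <- pairs$a[swap]; pairs$a[swap] <- pairs$b[swap]; pairs$b[swap] <- tmp
    pairs <- pairs[!duplicated(edgeKey(pairs$a, pairs$b)), , drop = FALSE]
    mi <- mapply(function(a, b) .miBits(bins[[a]], bins[[b]]),
                 pairs$a, pairs$b)
    # per-gene MI context: z-score of each pair within both genes' MI sets
    ids <- c(pairs$a, pairs$b)
    vals <- c(mi, mi)
    mu <- tapply(vals, ids, mean)
    sdv <- tapply(vals, ids, stats::sd)
    sdv[is.na(sdv) | sdv == 0] <- 1
    z <- (mi - mu[pairs$a]) / sdv[pairs$a] +
         (mi - mu[pairs$b]) / sdv[pairs$b]
    w <- as.numeric(z) / 2
    e <- expandUndirected(pairs, w)
    rel <- newRankedEdgeList(e$source, e$target, e$weight,
                             methodTag = "mi", directed = FALSE)
    rel
}

#' Pairwise mutual information of two vectors (bits)
#'
#' Equal-frequency discretization followed by the plug-in MI estimate, the
#' primitive behind [inferMiContext()]. Exposed for calibration tests.
#'
#' @param x,y numeric vectors of equal length.
#' @param nBins number of equal-frequency bins.
#' @return MI in bits.
#' @export
mutualInformation <- function(x, y, nBins = 8L) {
    .miBits(.binEqualFreq(x, nBins), .binEqualFreq(y, nBins))
}

#' Gaussian partial-correlation inference
#'
#' Estimates the precision matrix of the selected genes (optionally with a
#' diagonal shrinkage of the correlation matrix toward the identity) and
#' scores each gene pair by its partial correlation given all other genes.
#' Pairs with absolute partial correlation strictly above \code{threshold}
#' are kept (an edge exactly at the threshold is excluded); the weight is
#' the absolute partial correlation and each kept pair is emitted as two
#' opposing directed records sharing one rank.
#'
#' @param data expression input as in [inferTreeImportance()].
#' @param selection a \linkS4class{GeneSelection}.
#' @param threshold absolute partial-correlation cutoff (default 0.1).
#' @param lambda shrinkage weight in [0, 1) toward the identity correlation;
#'   0 requests the unregularized estimate, which fails with an explicit
#'   error when the covariance is singular (e.g. fewer cells than genes).
#' @return An undirected \linkS4class{RankedEdgeList}, tag \code{"pcor"}.
#' @export
inferPartialCorrelation <- function(data, selection, threshold = 0.1,
                                    lambda = 0) {
    expr <- .exprForInference(data, selection)
    genes <- rownames(expr)
    keepVar <- apply(expr, 1L, stats::var) > 0
    R <- diag(length(genes))
    dimnames(R) <- list(genes, genes)
    if (sum(keepVar) >= 2L) {
        Rv <- stats::cor(t(expr[keepVar, , drop = FALSE]))
        R[genes[keepVar], genes[keepVar]] <- Rv
    }
    if (lambda > 0) R <- (1 - lambda) * R + lambda * diag(length(genes))
    P <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(P) || !all(is.finite(P)))
        stop("singular covariance; rerun with shrinkage (lambda > 0), ",
             "e.g. lambda = 0.1")
    d <- sqrt(diag(P))
    pcor <- -P / outer(d, d)
    diag(pcor) <- 1
    tfs <- .selectionTfs(selection)
    pairs <- expand.grid(a = tfs, b = genes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    swap <- pairs$b %in% tfs & pairs$b < pairs$a
    tmp <- pairs$a[swap]; pairs$a[swap] <- pairs$b[swap]; pairs$b[swap] <- tmp
    pairs <- pairs[!duplicated(edgeKey(pairs$a, pairs$b)), , drop = FALSE]
    val <- abs(pcor[cbind(pairs$a, pairs$b)])
    keep <- val > threshold
    pairs <- pairs[keep, , drop = FALSE]
    e <- expandUndirected(pairs, val[keep])
    newRankedEdgeList(e$source, e$target, e$weight,
                      methodTag = "pcor", directed = FALSE)
}
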