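#' Identity (no-op) imputation baseline
#'
#' Returns the normalized matrix unchanged under the tag \code{"noimp"}.
#' This is the mandatory baseline of every experiment: its downstream EPR is
#' identical to the unimputed model, so its log2 EPR ratio is exactly 0.
#'
#' @param data a normalized \linkS4class{ExpressionDataset}.
#' @return An \linkS4class{ImputationResult} with tag \code{"noimp"}.
#' @export
imputeIdentity <- function(data) {
    m <- assay(data, "logcounts")
    methods::new("ImputationResult", matrix = m, methodTag = "noimp",
                 parameters = list())
}

# depth-normalize columns to the median depth and sqrt-transform, the
# variance-stabilized space in which neighbour distances are measured
.vstSpace <- function(cts) {
    depth <- colSums(cts)
    depth[depth == 0] <- 1
    sqrt(sweep(cts, 2L, stats::median(depth) / depth, `*`))
}

#' kNN-aggregation smoothing
#'
#' Stepwise smoothing of raw counts by aggregation over nearest neighbours.
#' At step s the raw counts of each cell are summed with those of its
#' min(2^s, k) + 1 nearest cells, nearest in Euclidean distance on the
#' square-root-transformed, depth-scaled aggregate of the previous step; the
#' neighbourhood doubles each step until k is reached. The aggregate is
#' finally rescaled to each cell's original depth. \code{k = 0} is the
#' identity.
#'
#' @param data an \linkS4class{ExpressionDataset} with raw counts.
#' @param k number of neighbours to aggregate over; must be < number of
#'   cells.
#' @return An \linkS4class{ImputationResult} with tag
#'   \code{"knn_aggregate"}, on the raw-count scale.
#' @export
imputeKnnAggregate <- function(data, k = 15L) {
    cts <- assay(data, "counts")
    k <- as.integer(k)
    if (k >= ncol(cts))
        stop("k must be smaller than the number of cells")
    if (k < 0L) stop("k must be >= 0")
    agg <- cts
    if (k > 0L) {
        nSteps <- max(1L, ceiling(log2(k)))
        for (s in seq_len(nSteps)) {
            kk <- min(2^s, k)
            d <- as.matrix(stats::dist(t(.vstSpace(agg))))
            agg <- matrix(0, nrow(cts), ncol(cts), dimnames = dimnames(cts))
            for (j in seq_len(ncol(cts))) {
                nb <- order(d[j, ])[seq_len(kk + 1L)]  # includes cell j
                agg[, j] <- rowSums(cts[, nb, drop = FALSE])
            }
        }
    }
    depth <- colSums(cts)
    aggDepth <- colSums(agg)
    aggDepth[aggDepth == 0] <- 1
    out <- sweep(agg, 2L, depth / aggDepth, `*`)
    methods::new("ImputationResult", matrix = out,
                 methodTag = "knn_aggregate",
                 parameters = list(k = k))
}

#' Diffusion smoothing on a cell-cell Markov graph
#'
#' Builds an adaptive Gaussian kernel between cells in the top principal
#' components of the normalized data (bandwidth of cell i set by its
#' distance to its knn-th neighbour), symmetrizes it, row-normalizes it into
#' a Markov matrix M, and returns expression diffused t steps:
#' \code{expr \%*\% t(M^t)}. \code{t = 0} is the identity; large t drives
#' every gene toward its stationary-weighted mean.
#'
#' @param data a normalized \linkS4class{ExpressionDataset}.
#' @param knn kernel bandwidth neighbour (must be < number of cells).
#' @param t number of diffusion steps.
#' @param nComponents number of principal components for the kernel space.
#' @return An \linkS4class{ImputationResult} with tag \code{"diffusion"}, on
#'   the normalized log scale.
#' @export
imputeDiffusion <- function(data, knn = 10L, t = 3L, nComponents = 20L) {
    expr <- assay(data, "logcounts")
    knn <- as.integer(knn); t <- as.integer(t)
    if (knn >= ncol(expr)) stop("knn must be smaller than the number of cells")
    if (knn < 1L) stop("knn must be >= 1")
    if (t < 0L) stop("t must be >= 0")
    if (t == 0L)
        return(methods::new("ImputationResult", matrix = expr,
                            methodTag = "diffusion",
                            parameters = list(knn = knn, t = t,
                                              nComponents = nComponents)))
    nc <- min(as.integer(nComponents), ncol(expr) - 1L, nrow(expr))
    pcs <- stats::prcomp(t(expr), center = TRUE, rank. = nc)$x
    d <- as.matrix(stats::dist(pcs))
    sigma <- apply(d, 1L, function(r) sort(r)[knn + 1L])
    sigma[sigma == 0] <- min(sigma[sigma > 0], 1)
    K <- exp(-d^2 / outer(sigma, sigma))
    K <- (K + t(K)) / 2  # symmetrize: connects otherwise one-way components
    M <- K / rowSums(K)
    Mt <- M
    if (t > 1L) for (i in seq_len(t - 1L)) Mt <- Mt %*% M
    out <- expr %*% t(Mt)
    dimnames(out) <- dimnames(expr)
    methods::new("ImputationResult", matrix = out, methodTag = "diffusion",
                 parameters = list(knn = knn, t = t, nComponents = nc))
}

#' Empirical-Bayes shrinkage imputation
#'
#' Gamma-Poisson posterior-mean denoising of raw counts. Each gene's
#' predicted normalized mean in each cell comes from a cross-gene ridge
#' regression of the gene on all other genes (solved jointly through the
#' regularized precision matrix); the output is the posterior mean
#' \code{(count + prior * mu) / (size_factor + prior)} on the normalized
#' scale. \code{prior -> 0} recovers the normalized raw counts;
#' \code{prior -> Inf} returns the predicted means.
#'
#' @param data a normalized \linkS4class{ExpressionDataset} (raw counts and
#'   size factors are taken from it).
#' @param priorStrength non-negative prior weight.
#' @param lambda ridge penalty of the cross-gene regression.
#' @return An \linkS4class{ImputationResult} with tag \code{"shrinkage"}.
#' @export
imputeShrinkage <- function(data, priorStrength = 1, lambda = 0.1) {
    if (priorStrength < 0) stop("priorStrength must be >= 0")
    cts <- assay(data, "counts")
    sf <- S4Vectors::metadata(data)$size_factors
    if (is.null(sf)) {
        libs <- colSums(cts)
        sf <- libs / stats::median(libs)
    }
    normed <- sweep(cts, 2L, sf, `/`)  # normalized raw counts
    mu <- .ridgePredictEachGene(normed, lambda)
    mu <- pmax(mu, 1e-8)
    post <- (cts + priorStrength * mu) /
        (matrix(sf, nrow(cts), ncol(cts), byrow = TRUE) + priorStrength)
    dimnames(post) <- dimnames(cts)
    methods::new("ImputationResult", matrix = post, methodTag = "shrinkage",
                 parameters = list(priorStrength = priorStrength,
                                   lambda = lambda))
}

# ridge prediction of every gene from all other genes, via the partitioned
# inverse of A = X'X + lambda I (so a single solve serves all genes):
# beta_g = -B[-g, g] / B[g, g] with B = A^{-1}
.ridgePredictEachGene <- function(normed, lambda) {
    X <- t(normed)                     # cells x genes
    ctr <- colMeans(X)
    Xc <- sweep(X, 2L, ctr)
    sdv <- apply(Xc, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(Xc, 2L, sdv, `/`)
    G <- ncol(Xs)
    A <- crossprod(Xs) + diag(lambda * nrow(Xs), G)
    B <- solve(A)
    Bdiag <- diag(B)
    # fitted (standardized) value of gene g = Xs %*% beta_g
    # computed jointly: F = -Xs %*% B scaled per column by 1/Bgg, plus the
    # g-th column's own contribution removed
    XB <- Xs %*% B
    Fhat <- -sweep(XB, 2L, Bdiag, `/`) + Xs
    pred <- sweep(sweep(Fhat, 2L, sdv, `*`), 2L, ctr, `+`)
    t(pred)
}

#' Import an externally imputed matrix
#'
#' Reads a genes x cells CSV (header = cell ids, first column = gene ids)
#' produced by an external imputation tool and checks it against the
#' dataset's gene and cell identifiers. Offending identifiers and negative
#' entries are reported explicitly.
#'
#' @param path CSV file path.
#' @param methodName label of the external method; the result is tagged
#'   \code{"external:<methodName>"}.
#' @param data the \linkS4class{ExpressionDataset} the matrix must match.
#' @return An \linkS4class{ImputationResult}.
#' @export
loadExternalImputed <- function(path, methodName, data) {
    m <- readCountsCsv(path)
    genes <- rownames(data); cells <- colnames(data)
    missG <- setdiff(genes, rownames(m))
    extraG <- setdiff(rownames(m), genes)
    if (length(missG) || length(extraG))
        stop("gene mismatch; missing: ",
             paste(missG, collapse = ", "), "; unexpected: ",
             paste(extraG, collapse = ", "))
    missC <- setdiff(cells, colnames(m))
    extraC <- setdiff(colnames(m), cells)
    if (length(missC) || length(extraC))
        stop("cell mismatch; missing: ",
             paste(missC, collapse = ", "), "; unexpected: ",
             paste(extraC, collapse = ", "))
    m <- m[genes, cells, drop = FALSE]
    if (any(m < 0))
        stop("negative entries at ",
             sum(m < 0), " positions; imputed values must be >= 0")
    methods::new("ImputationResult", matrix = m,
                 methodTag = paste0("external:", methodName),
                 parameters = list(path = path))
}
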