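#' Library-size normalization
#'
#' Scales every cell to the median library size of the dataset and applies a
#' \code{log1p} transform, storing the result as the \code{"logcounts"} assay
#' with layer tag \code{"normalized"}. Cells with zero total counts carry no
#' information and are rejected with a diagnostic naming them.
#'
#' @param data an \linkS4class{ExpressionDataset} with a raw counts layer.
#' @return The dataset with a \code{"logcounts"} assay added.
#' @examples
#' cfg <- SimulationConfig(nTfs = 5, nGenes = 30, nCells = 50, seed = 2)
#' ds <- normalizeCounts(simulateCounts(sampleGroundTruth(cfg), cfg))
#' layerTag(ds)
#' @export
normalizeCounts <- function(data) {
    cts <- assay(data, "counts")
    libs <- colSums(cts)
    if (any(libs == 0))
        stop("all-zero cell(s): ",
             paste(colnames(cts)[libs == 0], collapse = ", "))
    med <- stats::median(libs)
    norm <- log1p(sweep(cts, 2L, med / libs, `*`))
    out <- data
    assay(out, "logcounts") <- norm
    S4Vectors::metadata(out)$layer_tag <- "normalized"
    S4Vectors::metadata(out)$size_factors <- libs / med
    out
}

#' Smooth pseudotime trend of one gene
#'
#' Regresses expression on a fixed-knot natural cubic spline basis of
#' pseudotime (df = 5) and compares it with the intercept-only model by an
#' exact F-test. Variability across pseudotime is summarized as the deviance
#' (variance) explained by the smooth fit.
#'
#' @param expr numeric expression vector, one value per cell.
#' @param pt pseudotime vector, same length.
#' @param df spline degrees of freedom (default 5).
#' @return list with \code{deviance_explained} in [0, 1] and \code{p_value}
#'   of the F-test. A constant gene returns \code{(0, 1)}.
#' @examples
#' t <- seq(0, 1, length.out = 50)
#' fitPseudotimeTrend(sin(2 * pi * t) + rnorm(50, sd = 0.1), t)
#' @export
fitPseudotimeTrend <- function(expr, pt, df = 5L) {
    stopifnot(length(expr) == length(pt))
    if (length(expr) < 10L) stop("need at least 10 cells")
    if (!all(is.finite(expr)) || !all(is.finite(pt)))
        stop("expression and pseudotime must be finite")
    if (stats::var(expr) == 0)
        return(list(deviance_explained = 0, p_value = 1))
    basis <- splines::ns(pt, df = df)
    fit <- stats::lm.fit(cbind(1, basis), expr)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((expr - mean(expr))^2)
    dfree <- length(expr) - df - 1L
    f <- ((rss0 - rss1) / df) / (rss1 / dfree)
    p <- if (rss1 == 0) 0 else stats::pf(f, df, dfree, lower.tail = FALSE)
    list(deviance_explained = 1 - rss1 / rss0, p_value = p)
}

#' Select the inference gene universe
#'
#' Ranks genes by the deviance explained of their smooth pseudotime trend
#' and keeps the top \code{nTop} most variable genes; additionally keeps all
#' significantly varying TFs at Bonferroni-corrected p < \code{alpha}
#' (correction over the tested TFs). The final universe is the union and is
#' meant to be applied unchanged to every imputation layer of the dataset.
#'
#' @param data a normalized \linkS4class{ExpressionDataset}.
#' @param nTop number of most variable genes to keep (500 or 1000 typical).
#' @param alpha family-wise level for the TF test (default 0.01).
#' @param df spline degrees of freedom passed to [fitPseudotimeTrend()].
#' @return A \linkS4class{GeneSelection}.
#' @examples
#' cfg <- SimulationConfig(nTfs = 5, nGenes = 30, nCells = 60, seed = 2)
#' ds <- normalizeCounts(simulateCounts(sampleGroundTruth(cfg), cfg))
#' selectGenes(ds, nTop = 10)
#' @export
selectGenes <- function(data, nTop = 500L, alpha = 0.01, df = 5L) {
    if (!"logcounts" %in% assayNames(data))
        stop("normalized layer missing; run normalizeCounts() first")
    expr <- assay(data, "logcounts")
    pt <- pseudotime(data)
    tf <- tfFlags(data)
    genes <- rownames(expr)
    nTop <- as.integer(nTop)
    if (nTop > length(genes)) {
        warning("nTop exceeds the number of genes; returning all genes")
        nTop <- length(genes)
    }
    fits <- lapply(genes, function(g) fitPseudotimeTrend(expr[g, ], pt, df))
    dev <- vapply(fits, `[[`, numeric(1), "deviance_explained")
    praw <- vapply(fits, `[[`, numeric(1), "p_value")
    nTf <- sum(tf)
    pcorr <- ifelse(tf, pmin(1, praw * nTf), NA_real_)
    stats <- data.frame(gene = genes, is_tf = unname(tf),
                        deviance_explained = dev, p_value = praw,
                        p_bonferroni = pcorr, stringsAsFactors = FALSE)
    ord <- order(-dev, genes)  # deterministic tie-break on gene id
    hvg <- genes[ord][seq_len(nTop)]
    sigTf <- genes[tf & !is.na(pcorr) & pcorr < alpha]
    universe <- union(hvg, sigTf)
    methods::new("GeneSelection", hvgIds = hvg, sigTfIds = sigTf,
                 universe = universe, tfs = genes[tf], nTop = nTop,
                 alpha = alpha, stats = stats)
}
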