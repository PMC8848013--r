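#' Simulation configuration constructor
#'
#' Defaults describe a small benchmark-scale system: 10 TFs regulating a
#' 100-gene universe across 200 cells, a mean regulatory in-degree of 2,
#' moderate negative-binomial overdispersion and mean-dependent dropout.
#'
#' @param nTfs number of transcription factors.
#' @param nGenes total number of genes (TFs included).
#' @param nCells number of cells.
#' @param edgesPerGene mean regulatory in-degree per gene.
#' @param effectSize scale of the regulatory weights; 0 disconnects targets
#'   from their regulators (null model).
#' @param dispersion negative-binomial overdispersion phi
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param dropoutStrength scale of mean-dependent excess zeros: an entry with
#'   latent mean mu is zeroed with probability exp(-mu / dropoutStrength);
#'   0 disables excess zeros.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(nTfs = 5, nGenes = 40, nCells = 100, seed = 7)
#' @export
SimulationConfig <- function(nTfs = 10L, nGenes = 100L, nCells = 200L,
                             edgesPerGene = 2, effectSize = 2,
                             dispersion = 0.3, dropoutStrength = 1,
                             seed = 1L) {
    methods::new("SimulationConfig",
        nTfs = as.integer(nTfs), nGenes = as.integer(nGenes),
        nCells = as.integer(nCells), edgesPerGene = as.numeric(edgesPerGene),
        effectSize = as.numeric(effectSize),
        dispersion = as.numeric(dispersion),
        dropoutStrength = as.numeric(dropoutStrength),
        seed = as.integer(seed))
}

simGeneIds <- function(config) {
    tfs <- sprintf("TF%03d", seq_len(config@nTfs))
    targets <- sprintf("G%04d", seq_len(config@nGenes - config@nTfs))
    c(tfs, targets)
}

#' Sample a ground-truth TF -> gene network
#'
#' Draws a sparse directed network in which only TFs have outgoing edges.
#' Per-gene in-degrees are Poisson with mean \code{edgesPerGene}; regulators
#' are picked with probability proportional to a heavy-tailed (log-normal)
#' per-TF propensity, producing hub TFs. At least one TF->TF and one
#' TF->non-TF edge are guaranteed. Fully reproducible under
#' \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}; \code{nTfs >= 1} and
#'   \code{nTfs < nGenes} are required (a TF-free configuration cannot emit
#'   edges and is rejected by the validity check).
#' @return A \linkS4class{GroundTruthNetwork}.
#' @examples
#' net <- sampleGroundTruth(SimulationConfig(nTfs = 5, nGenes = 30, seed = 3))
#' net
#' @export
sampleGroundTruth <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    genes <- simGeneIds(config)
    tfs <- genes[seq_len(config@nTfs)]
    # heavy-tailed out-degree propensity -> hub TFs
    prop <- stats::rlnorm(length(tfs), meanlog = 0, sdlog = 1)
    src <- character(0); tgt <- character(0)
    for (g in genes) {
        avail <- setdiff(tfs, g)
        if (length(avail) == 0L) next
        d <- min(stats::rpois(1L, config@edgesPerGene), length(avail))
        if (d == 0L) next
        p <- prop[match(avail, tfs)]
        reg <- sample(avail, d, prob = p)
        src <- c(src, reg); tgt <- c(tgt, rep(g, d))
    }
    # guarantee the two edge species the evaluation conventions exercise
    nontf <- setdiff(genes, tfs)
    hasTfTf <- any(tgt %in% tfs)
    if (!hasTfTf && length(tfs) >= 2L) {
        pair <- sample(tfs, 2L)
        src <- c(src, pair[1L]); tgt <- c(tgt, pair[2L])
    }
    if (!any(tgt %in% nontf)) {
        src <- c(src, sample(tfs, 1L)); tgt <- c(tgt, sample(nontf, 1L))
    }
    keep <- !duplicated(edgeKey(src, tgt))
    e <- data.frame(source = src[keep], target = tgt[keep],
                    stringsAsFactors = FALSE)
    e <- e[order(e$source, e$target), , drop = FALSE]
    rownames(e) <- NULL
    methods::new("GroundTruthNetwork", tfs = tfs, genes = genes,
                 edges = e, directed = TRUE)
}

# smooth TF activity programs over pseudotime, in [0, 1]
tfProgram <- function(kind, t, center, scale) {
    switch(kind,
        sigmoid = 1 / (1 + exp(-(t - center) / scale)),
        pulse = exp(-(t - center)^2 / (2 * scale^2))
    )
}

#' Simulate single-cell counts from a ground-truth network
#'
#' TFs follow smooth pseudotime programs (random sigmoids and pulses);
#' each target's latent log-rate adds a weighted sum of its regulators'
#' standardized activities (weights of magnitude \code{effectSize}, random
#' sign). Counts are gamma-Poisson (negative binomial) around the latent
#' rate scaled by a log-normal per-cell library size, with mean-dependent
#' excess zeros. The latent rate matrix is kept as assay \code{"latent"} so
#' the regulatory covariance structure is directly testable.
#'
#' @param net a \linkS4class{GroundTruthNetwork} over the config's genes.
#' @param config the \linkS4class{SimulationConfig} used to draw it.
#' @return An \linkS4class{ExpressionDataset} with assays \code{"counts"}
#'   (integer) and \code{"latent"} (cell-scaled latent rates).
#' @examples
#' cfg <- SimulationConfig(nTfs = 5, nGenes = 30, nCells = 60, seed = 3)
#' ds <- simulateCounts(sampleGroundTruth(cfg), cfg)
#' ds
#' @export
simulateCounts <- function(net, config) {
    methods::validObject(config)
    stopifnot(all(net@genes %in% simGeneIds(config)))
    set.seed(config@seed + 1L)
    genes <- net@genes
    tfs <- net@tfs
    G <- length(genes); C <- config@nCells
    t <- stats::runif(C)

    # pulse-dominant mix: pulses at scattered centers decorrelate the TF
    # programs from one another far better than monotone sigmoids do
    kinds <- sample(c("sigmoid", "pulse"), length(tfs), replace = TRUE,
                    prob = c(0.3, 0.7))
    centers <- stats::runif(length(tfs), 0.1, 0.9)
    scales <- stats::runif(length(tfs), 0.05, 0.15)
    act <- matrix(0, length(tfs), C, dimnames = list(tfs, NULL))
    for (i in seq_along(tfs)) {
        p <- tfProgram(kinds[i], t, centers[i], scales[i])
        act[i, ] <- as.numeric(scale(p))  # standardized activity
    }

    w <- stats::runif(nrow(net@edges), 0.5, 1) *
        sample(c(-1, 1), nrow(net@edges), replace = TRUE) * config@effectSize

    base <- stats::rnorm(G, mean = log(1.5), sd = 0.4)
    logRate <- matrix(rep(base, C), G, C, dimnames = list(genes, NULL))
    for (i in seq_along(tfs))
        logRate[tfs[i], ] <- logRate[tfs[i], ] + 1.2 * act[i, ]
    if (nrow(net@edges) > 0 && config@effectSize > 0) {
        for (g in unique(net@edges$target)) {
            idx <- which(net@edges$target == g)
            reg <- act[net@edges$source[idx], , drop = FALSE]
            drive <- colSums(reg * w[idx]) / sqrt(length(idx))
            logRate[g, ] <- logRate[g, ] + tanh(drive / config@effectSize) *
                min(config@effectSize, 2)
        }
    }
    # cell-level biological variability beyond pseudotime, so latent rates
    # are non-degenerate even for unregulated genes
    logRate <- logRate + matrix(stats::rnorm(G * C, sd = 0.2), G, C)
    rate <- exp(logRate)

    libs <- stats::rlnorm(C, meanlog = 0, sdlog = 0.3)
    mu <- sweep(rate, 2L, libs, `*`)
    if (config@dispersion > 0) {
        shape <- 1 / config@dispersion
        mu_nb <- mu * matrix(stats::rgamma(G * C, shape = shape,
                                           rate = shape), G, C)
    } else mu_nb <- mu
    cts <- matrix(stats::rpois(G * C, lambda = mu_nb), G, C)
    if (config@dropoutStrength > 0) {
        pdrop <- exp(-mu / config@dropoutStrength)
        cts[matrix(stats::runif(G * C), G, C) < pdrop] <- 0L
    }
    dimnames(cts) <- list(genes, sprintf("cell%04d", seq_len(C)))
    ds <- ExpressionDataset(cts, tfFlags = genes %in% tfs, pseudotime = t,
                            layerTag = "raw")
    # latent rates without the library-size factor: the regulatory
    # covariance structure, untouched by technical depth variation
    assay(ds, "latent") <- `dimnames<-`(rate, dimnames(cts))
    ds
}

#' Binomial downsampling of a raw count matrix
#'
#' Replaces every raw count by a Binomial(count, fraction) draw, the standard
#' in-silico thinning used to lower sequencing depth (e.g. to 60% of the
#' original depth). The output is elementwise no larger than the input and
#' its expected total is \code{fraction} times the original total.
#'
#' @param data an \linkS4class{ExpressionDataset} with a raw counts layer.
#' @param fraction retention probability in (0, 1].
#' @param seed integer RNG seed.
#' @return A new \linkS4class{ExpressionDataset} with thinned counts.
#' @examples
#' cfg <- SimulationConfig(nTfs = 5, nGenes = 30, nCells = 50, seed = 2)
#' ds <- simulateCounts(sampleGroundTruth(cfg), cfg)
#' thin <- downsampleCounts(ds, 0.6, seed = 9)
#' sum(assay(thin, "counts")) / sum(assay(ds, "counts"))
#' @export
downsampleCounts <- function(data, fraction, seed = 1L) {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("fraction must be a single value in (0, 1]")
    cts <- assay(data, "counts")
    if (any(cts != round(cts)))
        stop("downsampling requires the raw integer count layer")
    if (fraction == 1) return(data)
    set.seed(as.integer(seed))
    thin <- matrix(stats::rbinom(length(cts), size = as.integer(cts),
                                 prob = fraction),
                   nrow(cts), ncol(cts), dimnames = dimnames(cts))
    out <- data
    assay(out, "counts") <- thin
    S4Vectors::metadata(out)$layer_tag <- "raw"
    S4Vectors::metadata(out)$downsample_fraction <- fraction
    out
}
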