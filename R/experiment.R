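#' Experiment configuration
#'
#' Describes one full factorial run: datasets x imputation operators x GRN
#' methods. The identity baseline (\code{"noimp"}) is mandatory — every
#' log2 ratio is taken against it.
#'
#' @param datasets named list of \linkS4class{SimulationConfig} objects (one
#'   simulated dataset each).
#' @param imputations character vector of imputation tags, subset of
#'   \code{c("noimp", "knn_aggregate", "diffusion", "shrinkage")}; must
#'   contain \code{"noimp"}.
#' @param grnMethods character vector, subset of
#'   \code{c("tree", "boost", "mi", "pcor")}.
#' @param nTop number of most variable genes to select.
#' @param alpha family-wise level of the TF test.
#' @param topNSimilarity edge count used for the Jaccard comparison.
#' @param downsampleFraction optional thinning fraction in (0, 1]
#'   (\code{NULL} disables the low-depth arm).
#' @param imputationParams,grnParams named lists of per-method parameter
#'   overrides.
#' @param masterSeed integer; per-cell seeds are derived from it and the
#'   cell labels, so adding a cell never perturbs the others.
#' @return validated config (a list with class \code{"ExperimentConfig"}).
#' @export
experimentConfig <- function(datasets,
                             imputations = c("noimp", "knn_aggregate",
                                             "diffusion", "shrinkage"),
                             grnMethods = c("tree", "mi", "pcor"),
                             nTop = 500L, alpha = 0.01,
                             topNSimilarity = 500L,
                             downsampleFraction = NULL,
                             imputationParams = list(),
                             grnParams = list(),
                             masterSeed = 1L) {
    stopifnot(length(datasets) >= 1L,
              all(vapply(datasets, methods::is, logical(1),
                         "SimulationConfig")))
    if (!"noimp" %in% imputations)
        stop("the 'noimp' baseline is mandatory")
    known <- c("noimp", "knn_aggregate", "diffusion", "shrinkage")
    if (!all(imputations %in% known))
        stop("unknown imputation tag(s): ",
             paste(setdiff(imputations, known), collapse = ", "))
    knownG <- c("tree", "boost", "mi", "pcor")
    if (!all(grnMethods %in% knownG))
        stop("unknown GRN tag(s): ",
             paste(setdiff(grnMethods, knownG), collapse = ", "))
    if (is.null(names(datasets)))
        names(datasets) <- paste0("sim", seq_along(datasets))
    if (!is.null(downsampleFraction))
        stopifnot(downsampleFraction > 0, downsampleFraction <= 1)
    structure(list(
        datasets = datasets, imputations = imputations,
        grnMethods = grnMethods, nTop = as.integer(nTop), alpha = alpha,
        topNSimilarity = as.integer(topNSimilarity),
        downsampleFraction = downsampleFraction,
        imputationParams = imputationParams, grnParams = grnParams,
        masterSeed = as.integer(masterSeed)), class = "ExperimentConfig")
}

.applyImputation <- function(tag, data, params, seed) {
    p <- params[[tag]]
    switch(tag,
        noimp = imputeIdentity(data),
        knn_aggregate = do.call(imputeKnnAggregate,
            c(list(data = data), if (is.null(p)) list(k = 7L) else p)),
        diffusion = do.call(imputeDiffusion,
            c(list(data = data), if (is.null(p)) list(knn = 10L, t = 3L) else p)),
        shrinkage = do.call(imputeShrinkage,
            c(list(data = data), if (is.null(p)) list() else p)),
        stop("unknown imputation tag: ", tag))
}

.applyGrn <- function(tag, imp, selection, params, seed) {
    p <- params[[tag]]
    rel <- switch(tag,
        tree = do.call(inferTreeImportance,
            c(list(data = imp, selection = selection, seed = seed),
              if (is.null(p)) list(nTrees = 100L) else p)),
        boost = do.call(inferBoosted,
            c(list(data = imp, selection = selection, seed = seed),
              if (is.null(p)) list() else p)),
        mi = do.call(inferMiContext,
            c(list(data = imp, selection = selection),
              if (is.null(p)) list() else p)),
        pcor = do.call(inferPartialCorrelation,
            c(list(data = imp, selection = selection),
              if (is.null(p)) list(lambda = 0.2) else p)),
        stop("unknown GRN tag: ", tag))
    rel@imputationTag <- methodTag(imp)
    rel
}

#' Run the full factorial experiment
#'
#' For every dataset: simulate counts and truth, normalize, select the gene
#' universe once (the same universe is applied to every imputation layer),
#' then for every imputation x GRN cell infer a ranked edge list, evaluate
#' it against the truth (top-k, TP/FP/FN, EP/EPR, density, degrees), and
#' attach log2 EPR ratios against the matched noimp baseline. Structure
#' (Jaccard/clustering/ARI, variance decomposition) and motif summaries are
#' computed across cells. All tables are written as tidy CSVs under
#' \code{outdir} together with a JSON manifest of seeds and parameters;
#' failed cells are recorded in the metrics table, never silently dropped.
#'
#' @param config an [experimentConfig()].
#' @param outdir output directory (created).
#' @return invisibly, a list with the tidy \code{metrics} data.frame,
#'   per-dataset artifacts, and the paths written.
#' @export
runExperiment <- function(config, outdir = tempfile("scgrn_run_")) {
    stopifnot(inherits(config, "ExperimentConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    rows <- list(); artifacts <- list()
    simEdges <- list()
    for (dsName in names(config$datasets)) {
        simCfg <- config$datasets[[dsName]]
        net <- sampleGroundTruth(simCfg)
        ds <- simulateCounts(net, simCfg)
        if (!is.null(config$downsampleFraction))
            ds <- downsampleCounts(ds, config$downsampleFraction,
                                   seed = deriveSeed(config$masterSeed,
                                                     dsName, "downsample"))
        ds <- normalizeCounts(ds)
        sel <- selectGenes(ds, nTop = min(config$nTop, nrow(ds)),
                           alpha = config$alpha)
        dsDir <- file.path(outdir, dsName)
        writeSimulatedDataset(ds, net, dsDir)
        cells <- list()
        for (impTag in config$imputations) {
            imp <- .applyImputation(impTag, ds, config$imputationParams,
                                    deriveSeed(config$masterSeed, dsName,
                                               impTag))
            for (grnTag in config$grnMethods) {
                seed <- deriveSeed(config$masterSeed, dsName, impTag, grnTag)
                cellLab <- paste(impTag, grnTag, sep = "/")
                res <- tryCatch({
                    rel <- .applyGrn(grnTag, imp, sel, config$grnParams,
                                     seed)
                    ev <- evaluateRanking(rel, net, sel)
                    writeRankedEdges(rel, file.path(
                        dsDir, sprintf("rankedEdges_%s_%s.tsv",
                                       impTag, grnTag)))
                    ev
                }, error = function(e) e)
                if (inherits(res, "error")) {
                    rows[[length(rows) + 1L]] <- data.frame(
                        dataset = dsName, imputation = impTag,
                        grn_method = grnTag, ep = NA_real_, epr = NA_real_,
                        density = NA_real_, k = NA_integer_,
                        n_reported = NA_integer_, n_tp = NA_integer_,
                        n_fp = NA_integer_, n_fn = NA_integer_,
                        log2_epr_ratio = NA_real_,
                        status = paste("failed:",
                                       conditionMessage(res)),
                        stringsAsFactors = FALSE)
                } else {
                    m <- res$metrics
                    cells[[cellLab]] <- res
                    rows[[length(rows) + 1L]] <- data.frame(
                        dataset = dsName, imputation = impTag,
                        grn_method = grnTag, ep = m@ep, epr = m@epr,
                        density = m@density, k = m@k,
                        n_reported = m@nReported, n_tp = m@nTp,
                        n_fp = m@nFp, n_fn = m@nFn,
                        log2_epr_ratio = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
                }
            }
        }
        artifacts[[dsName]] <- list(net = net, data = ds, selection = sel,
                                    cells = cells)
    }
    metrics <- do.call(rbind, rows)
    # log2 ratios vs the matched noimp baseline
    for (i in seq_len(nrow(metrics))) {
        if (metrics$status[i] != "ok") next
        base <- metrics[metrics$dataset == metrics$dataset[i] &
                        metrics$imputation == "noimp" &
                        metrics$grn_method == metrics$grn_method[i], ]
        if (nrow(base) == 1L && base$status == "ok" && base$epr > 0 &&
            metrics$epr[i] > 0)
            metrics$log2_epr_ratio[i] <- log2Ratio(metrics$epr[i], base$epr)
    }
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
    # structure analysis across cells, per dataset
    for (dsName in names(artifacts)) {
        a <- artifacts[[dsName]]
        topsets <- lapply(a$cells, function(res) {
            e <- edges(res$harmonized$pred)
            utils::head(e[order(e$rank), ], config$topNSimilarity)
        })
        if (length(topsets) >= 2L) {
            S <- similarityMatrix(topsets)
            utils::write.csv(as.data.frame(S),
                             file.path(outdir, dsName, "jaccard.csv"))
            artifacts[[dsName]]$similarity <- S
        }
        motifRows <- lapply(names(a$cells), function(lab) {
            res <- a$cells[[lab]]
            mc <- classifyMotifs(edges(res$topk), res$harmonized$ref)
            data.frame(model = lab, tp = mc@nTp, fp = mc@nFp, fn = mc@nFn,
                       unclassifiable = mc@nUnclassifiable,
                       loop_agree = mc@nLoopAgree,
                       tpr = mc@tpr, fdr = mc@fdr, stringsAsFactors = FALSE)
        })
        if (length(motifRows)) {
            mt <- do.call(rbind, motifRows)
            utils::write.csv(mt, file.path(outdir, dsName, "motifs.csv"),
                             row.names = FALSE)
            artifacts[[dsName]]$motifs <- mt
        }
    }
    manifest <- list(
        package_version = as.character(utils::packageVersion("scGRNimpact")),
        master_seed = config$masterSeed,
        n_top = config$nTop, alpha = config$alpha,
        top_n_similarity = config$topNSimilarity,
        downsample_fraction = config$downsampleFraction,
        imputations = config$imputations, grn_methods = config$grnMethods,
        datasets = lapply(config$datasets, function(cf)
            list(nTfs = cf@nTfs, nGenes = cf@nGenes, nCells = cf@nCells,
                 edgesPerGene = cf@edgesPerGene, effectSize = cf@effectSize,
                 dispersion = cf@dispersion,
                 dropoutStrength = cf@dropoutStrength, seed = cf@seed)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(list(metrics = metrics, artifacts = artifacts,
                   outdir = outdir))
}

#' Summarize a completed experiment directory
#'
#' Rebuilds the report tables from the persisted artifacts only (no hidden
#' state): the EPR table, the log2-ratio table, the variance/ANOVA
#' decomposition, the Jaccard/ARI comparison, and the motif summaries.
#'
#' @param outdir directory written by [runExperiment()].
#' @return list of report tables.
#' @export
reportExperiment <- function(outdir) {
    metricsPath <- file.path(outdir, "metrics.csv")
    if (!file.exists(metricsPath))
        stop("no metrics.csv in ", outdir, "; not a completed run")
    metrics <- utils::read.csv(metricsPath, stringsAsFactors = FALSE)
    ok <- metrics[metrics$status == "ok", , drop = FALSE]
    eprTable <- stats::reshape(
        ok[, c("dataset", "imputation", "grn_method", "epr")],
        idvar = c("dataset", "grn_method"), timevar = "imputation",
        direction = "wide")
    ratios <- ok[ok$imputation != "noimp" & !is.na(ok$log2_epr_ratio), ,
                 drop = FALSE]
    varDecomp <- NULL
    if (nrow(ratios) > 0 && length(unique(ratios$imputation)) > 1L &&
        length(unique(ratios$grn_method)) > 1L)
        varDecomp <- tryCatch(varianceByFactor(ratios),
                              error = function(e) NULL)
    ariTable <- NULL; jaccard <- list()
    for (dsName in unique(metrics$dataset)) {
        jp <- file.path(outdir, dsName, "jaccard.csv")
        if (!file.exists(jp)) next
        S <- as.matrix(utils::read.csv(jp, row.names = 1L,
                                       check.names = FALSE))
        jaccard[[dsName]] <- S
        labs <- rownames(S)
        impLab <- sub("/.*$", "", labs)
        grnLab <- sub("^.*/", "", labs)
        for (annot in c("imputation", "grn")) {
            lab <- if (annot == "imputation") impLab else grnLab
            nCl <- length(unique(lab))
            if (nCl < 2L || nCl > nrow(S)) next
            cl <- clusterModels(S, nCl)
            ariTable <- rbind(ariTable, data.frame(
                dataset = dsName, annotation = annot,
                ari = clusterPurityAri(cl, lab), stringsAsFactors = FALSE))
        }
    }
    motifs <- list()
    for (dsName in unique(metrics$dataset)) {
        mp <- file.path(outdir, dsName, "motifs.csv")
        if (file.exists(mp))
            motifs[[dsName]] <- utils::read.csv(mp, stringsAsFactors = FALSE)
    }
    failed <- metrics[metrics$status != "ok", , drop = FALSE]
    list(metrics = metrics, epr_table = eprTable, log2_ratios = ratios,
         variance = varDecomp, jaccard = jaccard, ari = ariTable,
         motifs = motifs, failed_cells = failed)
}
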