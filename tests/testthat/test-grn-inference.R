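test_that("competition ranking follows the min-rank tie rule", {
    expect_equal(competitionRank(c(5, 4, 4, 3)), c(1L, 2L, 2L, 4L))
    expect_equal(competitionRank(numeric(0)), integer(0))
    expect_error(competitionRank(c(1, NA)), "NA")
})

test_that("ranks are a deterministic function of weights, not row order", {
    set.seed(5)
    src <- rep(paste0("TF", 1:3), each = 4)
    tgt <- rep(paste0("g", 1:4), times = 3)
    w <- runif(12)
    r1 <- makeRanking(src, tgt, w)
    perm <- sample(12)
    r2 <- makeRanking(src[perm], tgt[perm], w[perm])
    e1 <- edges(r1); e2 <- edges(r2)
    key <- paste(e1$source, e1$target)
    expect_equal(e1$rank, e2$rank[match(key, paste(e2$source, e2$target))])
})

test_that("tree importance finds a perfect predictor and ignores constants", {
    set.seed(8)
    n <- 80
    tf1 <- rnorm(n); tf2 <- rnorm(n); tf3 <- rnorm(n)
    m <- rbind(TF1 = tf1, TF2 = tf2, TF3 = tf3,
               gA = tf1,                 # exact copy of TF1
               gB = rep(2, n))           # constant target
    colnames(m) <- paste0("c", 1:n)
    sel <- makeSelection(rownames(m), c("TF1", "TF2", "TF3"))
    ds <- makeDataset(pmax(round(exp(m)), 0), tfs = c("TF1", "TF2", "TF3"))
    res <- new("ImputationResult", matrix = m - min(m), methodTag = "noimp",
               parameters = list())
    rel <- inferTreeImportance(res, sel, nTrees = 100, seed = 1)
    e <- edges(rel)
    eA <- e[e$target == "gA", ]
    expect_equal(eA$source[which.max(eA$weight)], "TF1")
    expect_true(all(e$weight[e$target == "gB"] == 0))
})

test_that("boosted inference is deterministic and agrees with the forest", {
    rel1 <- inferBoosted(smallData, smallSel, seed = 4)
    rel2 <- inferBoosted(smallData, smallSel, seed = 4)
    expect_identical(edges(rel1), edges(rel2))

    tree <- inferTreeImportance(smallData, smallSel, nTrees = 100, seed = 4)
    top <- function(rel, n) {
        e <- edges(rel)
        head(paste(e$source, e$target)[order(e$rank)], n)
    }
    jac <- function(a, b)
        length(intersect(a, b)) / length(union(a, b))
    e <- edges(tree)
    set.seed(1)
    rnd <- sample(paste(e$source, e$target), 50)
    expect_gt(jac(top(rel1, 50), top(tree, 50)), jac(top(rel1, 50), rnd))
})

test_that("mutual information matches the identity channel and is
           invariant to monotone maps", {
    set.seed(2)
    x <- rnorm(4000)
    expect_equal(mutualInformation(x, x, nBins = 8), 3, tolerance = 1e-10)
    expect_equal(mutualInformation(x, -x, nBins = 8),
                 mutualInformation(x, x, nBins = 8), tolerance = 1e-10)
    expect_equal(mutualInformation(x, exp(x), nBins = 8),
                 mutualInformation(x, x, nBins = 8), tolerance = 1e-10)
})

test_that("finite-sample MI of independent genes stays below its
           permutation null quantile", {
    set.seed(10)
    x <- rnorm(300); y <- rnorm(300)
    obs <- mutualInformation(x, y, nBins = 6)
    null <- vapply(1:200, function(i)
        mutualInformation(x, sample(y), nBins = 6), numeric(1))
    expect_gt(obs, 0)  # plug-in estimate is positively biased
    expect_lt(obs, quantile(null, 0.95) + 1e-12)
})

test_that("MI-context edge lists are undirected with shared ranks", {
    rel <- inferMiContext(smallData, smallSel, nBins = 6)
    e <- edges(rel)
    expect_false(rel@directed)
    key <- paste(e$source, e$target)
    rev <- paste(e$target, e$source)
    both <- match(rev, key)
    tfPairs <- e$source %in% smallSel@tfs & e$target %in% smallSel@tfs
    # every TF-TF pair appears in both directions at one shared rank
    expect_true(all(!is.na(both[tfPairs])))
    expect_equal(e$rank[tfPairs], e$rank[both[tfPairs]])
})

test_that("partial correlation separates a chain from its shortcut", {
    set.seed(3)
    n <- 2000
    x <- rnorm(n); y <- 0.9 * x + rnorm(n, sd = sqrt(1 - 0.81))
    z <- 0.9 * y + rnorm(n, sd = sqrt(1 - 0.81))
    m <- rbind(TFX = x, TFY = y, gZ = z)
    colnames(m) <- paste0("c", 1:n)
    sel <- makeSelection(rownames(m), c("TFX", "TFY"))
    res <- new("ImputationResult", matrix = m - min(m), methodTag = "noimp",
               parameters = list())
    rel <- inferPartialCorrelation(res, sel, threshold = 0.1)
    e <- edges(rel)
    keys <- paste(e$source, e$target)
    expect_true("TFX TFY" %in% keys)
    expect_true("TFY gZ" %in% keys)
    # marginally corr(X, Z) ~ 0.81, but the partial correlation given Y
    # vanishes, so the shortcut is not reported above the 0.1 threshold
    expect_gt(cor(x, z), 0.5)
    expect_false("TFX gZ" %in% keys)
})

test_that("an edge exactly at the partial-correlation threshold is excluded", {
    # a 2-gene system whose sample correlation (= pcor) is exactly 0.1
    r <- 0.1
    set.seed(4); n <- 500
    x <- scale(rnorm(n))[, 1]
    y0 <- scale(residuals(lm(rnorm(n) ~ x)))[, 1]
    y <- r * x + sqrt(1 - r^2) * y0
    m <- rbind(TFA = x, gB = y)
    colnames(m) <- paste0("c", 1:n)
    expect_equal(cor(x, y), r, tolerance = 1e-12)
    sel <- makeSelection(rownames(m), "TFA")
    res <- new("ImputationResult", matrix = m - min(m), methodTag = "noimp",
               parameters = list())
    # recover the pipeline's own |pcor| for the pair, then probe the cutoff
    w <- edges(inferPartialCorrelation(res, sel, threshold = 0))$weight[1]
    expect_equal(w, r, tolerance = 1e-10)
    rel <- inferPartialCorrelation(res, sel, threshold = w)
    expect_equal(nrow(edges(rel)), 0L)  # "higher than", not "at least"
    rel2 <- inferPartialCorrelation(res, sel, threshold = w - 1e-9)
    expect_equal(nrow(edges(rel2)), 2L)
})

test_that("singular covariance demands explicit regularization", {
    set.seed(6)
    m <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
    sel <- makeSelection(rownames(m), paste0("g", 1:5))
    res <- new("ImputationResult", matrix = m - min(m), methodTag = "noimp",
               parameters = list())
    expect_error(inferPartialCorrelation(res, sel, lambda = 0), "shrinkage")
    expect_s4_class(inferPartialCorrelation(res, sel, lambda = 0.5),
                    "RankedEdgeList")
})

test_that("external ranked edge lists are parsed and re-ranked", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "ranked.tsv")
    writeLines(c("Gene1\tGene2\tEdgeWeight",
                 "TF1\tg1\t5", "TF1\tg2\t4", "TF2\tg1\t4", "TF2\tg2\t3"), p)
    rel <- loadExternalRankedEdges(p)
    expect_equal(edges(rel)$rank, c(1L, 2L, 2L, 4L))

    writeLines("Gene1\tGene2\tEdgeWeight", p)
    expect_warning(empty <- loadExternalRankedEdges(p), "empty")
    expect_equal(nrow(edges(empty)), 0L)

    writeLines(c("Gene1\tGene2\tEdgeWeight",
                 "TF1\tg1\t5", "TF1\tg1\t4"), p)
    expect_error(loadExternalRankedEdges(p), "duplicate")

    writeLines(c("Gene1\tGene2\tEdgeWeight", "TF1\tg1\tNaN"), p)
    expect_error(loadExternalRankedEdges(p), "line")
})

test_that("scoring methods beat chance on simulated regulatory data", {
    eprs <- vapply(1:10, function(s) {
        cfg <- SimulationConfig(nTfs = 8, nGenes = 50, nCells = 120,
                                effectSize = 2.5, seed = s + 100)
        net <- sampleGroundTruth(cfg)
        ds <- normalizeCounts(simulateCounts(net, cfg))
        sel <- selectGenes(ds, nTop = 50)
        evaluateRanking(inferTreeImportance(ds, sel, nTrees = 50,
                                            seed = 1), net, sel)$metrics@epr
    }, numeric(1))
    expect_lt(stats::wilcox.test(eprs, mu = 1,
                                 alternative = "greater")$p.value, 0.01)
})

test_that("on permuted expression the mean EPR is statistically one", {
    cfg <- SimulationConfig(nTfs = 5, nGenes = 30, nCells = 80,
                            effectSize = 2, seed = 31)
    net <- sampleGroundTruth(cfg)
    ds <- normalizeCounts(simulateCounts(net, cfg))
    sel <- selectGenes(ds, nTop = 30)
    expr <- assay(ds, "logcounts")
    eprs <- vapply(1:60, function(r) {
        set.seed(r)
        perm <- apply(expr, 1, sample)  # break all gene-gene dependence
        m <- t(perm)
        dimnames(m) <- dimnames(expr)
        res <- new("ImputationResult", matrix = m - min(m),
                   methodTag = "noimp", parameters = list())
        rel <- inferPartialCorrelation(res, sel, lambda = 0.2)
        if (nrow(edges(rel)) == 0) return(NA_real_)
        evaluateRanking(rel, net, sel)$metrics@epr
    }, numeric(1))
    eprs <- eprs[!is.na(eprs)]
    se <- sd(eprs) / sqrt(length(eprs))
    expect_lt(abs(mean(eprs) - 1), 3 * se + 0.05)
})
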