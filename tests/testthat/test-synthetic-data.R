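test_that("degenerate configurations are rejected", {
    expect_error(SimulationConfig(nTfs = 0, nGenes = 10), "nTfs")
    expect_error(SimulationConfig(nTfs = 10, nGenes = 10), "smaller")
    expect_error(SimulationConfig(edgesPerGene = 0), "edgesPerGene")
})

test_that("ground-truth sampling is reproducible and respects invariants", {
    cfg <- SimulationConfig(nTfs = 5, nGenes = 50, seed = 42)
    n1 <- sampleGroundTruth(cfg)
    n2 <- sampleGroundTruth(cfg)
    expect_identical(edges(n1), edges(n2))
    e <- edges(n1)
    expect_true(all(e$source %in% tfSet(n1)))
    expect_false(any(e$source == e$target))
    expect_equal(anyDuplicated(paste(e$source, e$target)), 0L)
    # both edge species the evaluation conventions rely on are present
    expect_true(any(e$target %in% tfSet(n1)))
    expect_true(any(!e$target %in% tfSet(n1)))
})

test_that("mean in-degree tracks edgesPerGene over replicates", {
    degs <- vapply(1:100, function(s) {
        net <- sampleGroundTruth(SimulationConfig(
            nTfs = 5, nGenes = 50, edgesPerGene = 2, seed = s))
        nrow(edges(net)) / length(geneSet(net))
    }, numeric(1))
    # Poisson(2) truncated at the 5 available TFs biases slightly downward
    expect_equal(mean(degs), 2, tolerance = 0.05)
})

test_that("simulated counts are integer, non-negative and seeded", {
    cts <- assay(fixtureData, "counts")
    expect_true(all(cts >= 0))
    expect_true(all(cts == round(cts)))
    ds2 <- simulateCounts(fixtureNet, fixtureCfg)
    expect_identical(assay(ds2, "counts"), cts)
    expect_true(all(pseudotime(fixtureData) >= 0 &
                    pseudotime(fixtureData) <= 1))
})

test_that("dropout and dispersion increase the zero fraction", {
    cfgNoisy <- SimulationConfig(nTfs = 5, nGenes = 40, nCells = 120,
                                 dispersion = 0.5, dropoutStrength = 3,
                                 seed = 5)
    cfgClean <- SimulationConfig(nTfs = 5, nGenes = 40, nCells = 120,
                                 dispersion = 0, dropoutStrength = 0,
                                 seed = 5)
    net <- sampleGroundTruth(cfgClean)
    zNoisy <- mean(assay(simulateCounts(net, cfgNoisy), "counts") == 0)
    zClean <- mean(assay(simulateCounts(net, cfgClean), "counts") == 0)
    expect_gt(zNoisy, zClean)
})

test_that("in the Poisson limit counts scatter around the latent rates", {
    cfg <- SimulationConfig(nTfs = 5, nGenes = 40, nCells = 400,
                            dispersion = 0, dropoutStrength = 0, seed = 3)
    ds <- simulateCounts(sampleGroundTruth(cfg), cfg)
    cts <- assay(ds, "counts")
    lat <- assay(ds, "latent")
    expect_gt(cor(as.numeric(cts), as.numeric(lat)), 0.55)
    # without dropout the zero fraction is what the count law itself gives:
    # bounded by the Poisson zero mass at the latent rates (libraries vary,
    # so allow modest slack)
    expect_lt(mean(cts == 0), mean(exp(-lat)) + 0.1)
})

test_that("true edges carry more latent correlation than non-edges", {
    pvals <- vapply(1:10, function(s) {
        cfg <- SimulationConfig(nTfs = 8, nGenes = 50, nCells = 120,
                                effectSize = 2.5, seed = s)
        net <- sampleGroundTruth(cfg)
        ds <- simulateCounts(net, cfg)
        lat <- assay(ds, "latent")
        e <- edges(net)
        ce <- mapply(function(a, b) abs(cor(lat[a, ], lat[b, ])),
                     e$source, e$target)
        set.seed(s + 1000)
        key <- paste(e$source, e$target)
        g <- rownames(ds)
        ne <- replicate(200, {
            repeat {
                p <- sample(g, 2)
                if (!paste(p[1], p[2]) %in% key) break
            }
            abs(cor(lat[p[1], ], lat[p[2], ]))
        })
        stats::wilcox.test(ce, ne, alternative = "greater")$p.value
    }, numeric(1))
    # pooled evidence across seeds (Fisher's method)
    chisq <- -2 * sum(log(pmax(pvals, 1e-300)))
    pooled <- stats::pchisq(chisq, df = 2 * length(pvals),
                            lower.tail = FALSE)
    expect_lt(pooled, 0.01)
    expect_gt(mean(pvals < 0.05), 0.5)
})

test_that("effectSize 0 removes the edge/non-edge correlation contrast", {
    cfg <- SimulationConfig(nTfs = 8, nGenes = 50, nCells = 200,
                            effectSize = 0, seed = 2)
    net <- sampleGroundTruth(cfg)
    ds <- simulateCounts(net, cfg)
    lat <- assay(ds, "latent")
    e <- edges(net)
    nonTf <- setdiff(rownames(ds), tfSet(net))
    eNon <- e[e$target %in% nonTf, ]
    ce <- mapply(function(a, b) abs(cor(lat[a, ], lat[b, ])),
                 eNon$source, eNon$target)
    set.seed(9)
    ne <- replicate(300, {
        abs(cor(lat[sample(tfSet(net), 1), ], lat[sample(nonTf, 1), ]))
    })
    expect_lt(abs(mean(ce) - mean(ne)), 0.02)
})

test_that("downsampling obeys the binomial thinning contract", {
    cts <- assay(fixtureData, "counts")
    full <- downsampleCounts(fixtureData, 1.0)
    expect_identical(assay(full, "counts"), cts)

    thin <- downsampleCounts(fixtureData, 0.6, seed = 3)
    tc <- assay(thin, "counts")
    expect_true(all(tc <= cts))
    expect_true(all(tc >= 0))
    # same seed -> identical; thinning is elementwise dominated
    expect_identical(assay(downsampleCounts(fixtureData, 0.6, seed = 3),
                           "counts"), tc)
    expect_error(downsampleCounts(fixtureData, 0), "fraction")
    expect_error(downsampleCounts(fixtureData, 1.2), "fraction")
})

test_that("thinning a single large entry matches the binomial mean", {
    m <- matrix(10L, 1, 1, dimnames = list("g1", "c1"))
    ds <- makeDataset(m)
    draws <- vapply(1:2000, function(s)
        as.numeric(assay(downsampleCounts(ds, 0.5, seed = s), "counts")),
        numeric(1))
    # Binomial(10, 0.5): mean 5, sd sqrt(2.5); 2000 draws -> SE 0.035
    expect_equal(mean(draws), 5, tolerance = 3 * sqrt(2.5 / 2000))
})

test_that("simulated datasets round-trip through the CSV/TSV writers", {
    dir <- withr::local_tempdir()
    paths <- writeSimulatedDataset(fixtureData, fixtureNet, dir)
    m <- readCountsCsv(paths[["counts"]])
    expect_equal(m, assay(fixtureData, "counts"), ignore_attr = FALSE)
    ref <- readReferenceNetwork(paths[["truth"]],
                                tfs = tfSet(fixtureNet),
                                genes = geneSet(fixtureNet))
    expect_setequal(paste(edges(ref)$source, edges(ref)$target),
                    paste(edges(fixtureNet)$source,
                          edges(fixtureNet)$target))
})
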