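test_that("Jaccard similarity is intersection over union", {
    a <- data.frame(source = c("x", "y"), target = c("1", "2"))
    expect_equal(jaccardSimilarity(a, a), 1)
    b <- data.frame(source = c("p", "q"), target = c("1", "2"))
    expect_equal(jaccardSimilarity(a, b), 0)
    expect_equal(jaccardSimilarity(paste0("e", 1:500),
                                   paste0("e", 251:750)), 250 / 750)
    expect_warning(j <- jaccardSimilarity(character(0), character(0)),
                   "convention")
    expect_equal(j, 1)
})

test_that("model clustering recovers replicated groups whatever the order", {
    mk <- function(ids) data.frame(source = ids, target = ids)
    sets <- list(a1 = mk(paste0("p", 1:20)), a2 = mk(paste0("p", 1:20)),
                 b1 = mk(paste0("q", 1:20)), b2 = mk(paste0("q", 1:20)))
    S <- similarityMatrix(sets)
    expect_true(isSymmetric(S))
    expect_equal(diag(S), setNames(rep(1, 4), names(sets)))
    cl <- clusterModels(S, 2)
    expect_equal(cl[["a1"]], cl[["a2"]])
    expect_equal(cl[["b1"]], cl[["b2"]])
    expect_false(cl[["a1"]] == cl[["b1"]])

    perm <- c(3, 1, 4, 2)
    cl2 <- clusterModels(S[perm, perm], 2)
    expect_equal(clusterPurityAri(cl[names(cl2)], cl2), 1)
    expect_error(clusterModels(S, 9), "exceeds")
})

test_that("ARI is 1 for identical partitions and ~0 at chance", {
    expect_equal(clusterPurityAri(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
    set.seed(3)
    aris <- replicate(1000,
        clusterPurityAri(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE)))
    expect_lt(abs(mean(aris)), 0.02)
    expect_error(clusterPurityAri(1, 2), "two elements")
})

test_that("variance decomposition isolates the varying factor", {
    grid <- expand.grid(dataset = "d1",
                        imputation = paste0("imp", 1:4),
                        grn_method = paste0("grn", 1:3),
                        stringsAsFactors = FALSE)
    # ratios depend only on the GRN method
    grid$log2_epr_ratio <- as.numeric(factor(grid$grn_method))
    vd <- varianceByFactor(grid)
    expect_true(all(vd$var_imputation_fixed$variance > 0))
    expect_true(all(vd$var_grn_fixed$variance == 0))

    allEq <- grid; allEq$log2_epr_ratio <- 0.3
    vd0 <- varianceByFactor(allEq)
    expect_true(all(c(vd0$var_grn_fixed$variance,
                      vd0$var_imputation_fixed$variance) == 0))
    expect_equal(vd0$wilcoxon_p, 1)

    expect_error(varianceByFactor(grid[-1, ]), "missing cells")
})

test_that("the two-way ANOVA attributes variance to the injected factor", {
    set.seed(5)
    grid <- expand.grid(dataset = "d1",
                        imputation = paste0("imp", 1:4),
                        grn_method = paste0("grn", 1:3),
                        stringsAsFactors = FALSE)
    impEff <- setNames(rnorm(4, sd = 1), paste0("imp", 1:4))
    grnEff <- setNames(rnorm(3, sd = 0.25), paste0("grn", 1:3))
    grid$log2_epr_ratio <- impEff[grid$imputation] +
        grnEff[grid$grn_method] + rnorm(nrow(grid), sd = 0.05)
    an <- varianceByFactor(grid)$anova[["d1"]]
    pImp <- an$p_value[an$factor == "imputation"]
    pGrn <- an$p_value[an$factor == "grn_method"]
    expect_lt(pImp, pGrn)
    # cross-check against R's own sequential ANOVA on the same data
    ref <- summary(aov(log2_epr_ratio ~ grn_method + imputation,
                       data = grid))[[1]]
    expect_equal(pImp, ref$`Pr(>F)`[2])
})

test_that("rank shifts match a brute-force lookup and flag missing edges", {
    before <- makeRanking(rep("TF1", 10), paste0("g", 1:10), 10:1)
    after <- makeRanking(rep("TF1", 10), paste0("g", 1:10), 1:10)
    tp <- edges(topK(before, 10))
    rs <- rankShift(tp, after)
    expect_equal(rs$rank_after[rs$target == "g1"], 10L)   # reversed
    expect_equal(rs$rank_after[rs$target == "g10"], 1L)

    same <- rankShift(tp, before)
    expect_true(all(same$rank_after - same$rank_before == 0))

    # brute-force median shift on a toy ranking
    set.seed(8)
    wA <- runif(20); wB <- runif(20)
    rA <- makeRanking(rep("TF1", 20), paste0("g", 1:20), wA)
    rB <- makeRanking(rep("TF1", 20), paste0("g", 1:20), wB)
    tpA <- edges(topK(rA, 8))
    got <- rankShift(tpA, rB)
    brute <- vapply(seq_len(nrow(tpA)), function(i) {
        eB <- edges(rB)
        eB$rank[eB$target == tpA$target[i]]
    }, integer(1))
    expect_equal(got$rank_after, brute)
    expect_equal(median(got$rank_after - got$rank_before),
                 median(brute - tpA$rank))

    # an edge absent from the imputed ranking gets the sentinel rank
    short <- makeRanking(rep("TF1", 5), paste0("g", 1:5), 5:1)
    rs2 <- rankShift(tp, short, universeSize = 10)
    expect_true(all(rs2$rank_after[rs2$missing_after] == 11L))
})

test_that("correlation-class regression is y = x under identity imputation", {
    m <- assay(fixtureData, "logcounts")
    ev <- evaluateRanking(
        inferPartialCorrelation(fixtureData, fixtureSel, lambda = 0.2),
        fixtureNet, fixtureSel)
    ccr <- correlationClassRegression(m, m, ev$classification)
    expect_equal(ccr$table$cor_before, ccr$table$cor_after)
    ln <- ccr$lines
    for (cl in ln$class[!is.na(ln$slope)]) {
        expect_equal(ln$slope[ln$class == cl], 1, tolerance = 1e-8)
        expect_equal(ln$intercept[ln$class == cl], 0, tolerance = 1e-8)
    }
})

test_that("degenerate classes and constant genes are flagged, not fitted", {
    cls <- new("EdgeClassification",
               tp = data.frame(source = "g1", target = "g2"),
               fp = data.frame(source = "g1", target = "g3"),
               fn = data.frame(source = character(0),
                               target = character(0)),
               k = 1L, nReported = 2L)
    set.seed(1)
    before <- rbind(g1 = rnorm(20), g2 = rnorm(20), g3 = rep(1, 20))
    colnames(before) <- paste0("c", 1:20)
    ccr <- correlationClassRegression(before, before, cls)
    expect_true(ccr$table$degenerate[ccr$table$target == "g3"])
    expect_true(all(is.na(ccr$lines$slope)))  # every class has < 2 edges
})

test_that("absolute correlations equal a two-pass Pearson oracle", {
    set.seed(2)
    m <- matrix(rnorm(200), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
    cls <- new("EdgeClassification",
               tp = data.frame(source = paste0("g", 1:5),
                               target = paste0("g", 6:10)),
               fp = data.frame(source = character(0),
                               target = character(0)),
               fn = data.frame(source = character(0),
                               target = character(0)),
               k = 5L, nReported = 5L)
    ccr <- correlationClassRegression(m, m, cls)
    twoPass <- function(x, y) {
        mx <- mean(x); my <- mean(y)
        sum((x - mx) * (y - my)) /
            sqrt(sum((x - mx)^2) * sum((y - my)^2))
    }
    oracle <- vapply(1:5, function(i)
        abs(twoPass(m[paste0("g", i), ], m[paste0("g", i + 5), ])),
        numeric(1))
    expect_equal(ccr$table$cor_before, oracle, tolerance = 1e-12)
})
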