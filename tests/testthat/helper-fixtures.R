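# shared fixtures, built once per test run

fixtureCfg <- SimulationConfig(nTfs = 8L, nGenes = 60L, nCells = 150L,
                               edgesPerGene = 2, effectSize = 2.5,
                               dispersion = 0.3, dropoutStrength = 1,
                               seed = 11L)
fixtureNet <- sampleGroundTruth(fixtureCfg)
fixtureData <- normalizeCounts(simulateCounts(fixtureNet, fixtureCfg))
fixtureSel <- selectGenes(fixtureData, nTop = 60L)

# a small, fast fixture for the tree/boosting methods
smallCfg <- SimulationConfig(nTfs = 5L, nGenes = 25L, nCells = 100L,
                             effectSize = 2.5, seed = 7L)
smallNet <- sampleGroundTruth(smallCfg)
smallData <- normalizeCounts(simulateCounts(smallNet, smallCfg))
smallSel <- selectGenes(smallData, nTop = 25L)

# a GeneSelection over an explicit universe, for hand-built matrices
makeSelection <- function(genes, tfs) {
    new("GeneSelection", hvgIds = genes, sigTfIds = character(0),
        universe = genes, tfs = tfs, nTop = length(genes), alpha = 0.01,
        stats = data.frame())
}

# RankedEdgeList from explicit vectors (ranks recomputed from weights)
makeRanking <- function(source, target, weight, directed = TRUE) {
    scGRNimpact:::newRankedEdgeList(source, target, weight,
                                    directed = directed)
}

# an ExpressionDataset from a plain matrix (uniform pseudotime)
makeDataset <- function(m, tfs = character(0)) {
    ExpressionDataset(m, tfFlags = rownames(m) %in% tfs,
                      pseudotime = seq(0, 1, length.out = ncol(m)))
}

# ground truth from explicit edges
makeTruth <- function(src, tgt, tfs, genes) {
    new("GroundTruthNetwork", tfs = tfs, genes = genes,
        edges = data.frame(source = src, target = tgt,
                           stringsAsFactors = FALSE),
        directed = TRUE)
}

# brute-force ordered-triple motif scan (independent oracle)
bruteForceMotifs <- function(edgeDf) {
    key <- paste(edgeDf$source, edgeDf$target)
    nodes <- unique(c(edgeDf$source, edgeDf$target))
    out <- data.frame(X = character(0), Y = character(0), Z = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
    for (x in nodes) for (y in nodes) for (z in nodes) {
        if (x == y || y == z || x == z) next
        if (paste(x, y) %in% key && paste(y, z) %in% key) {
            kind <- if (paste(x, z) %in% key) "ffl" else "chain"
            out <- rbind(out, data.frame(X = x, Y = y, Z = z, kind = kind))
        }
    }
    out[order(out$X, out$Y, out$Z), , drop = FALSE]
}
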