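# scGRNimpact

Benchmarking how single-cell RNA-seq **imputation** changes downstream
**gene regulatory network (GRN) reconstruction**.

Imputation methods replace technical dropout zeros in scRNA-seq count
matrices by smoothed or model-based estimates. Doing so also reshapes
gene–gene correlations — often inflating them — and GRN inference methods
score candidate TF → target edges from exactly those dependencies. This
package provides a self-contained pipeline to quantify that interaction:
a synthetic single-cell simulator with a known ground-truth network,
light-weight imputation operators from three mechanistic families,
four ranked-edge GRN scoring methods, and the full evaluation suite
(early precision ratios, log2 performance ratios, network-structure and
motif comparisons). It is aimed at methodologists who want a controlled,
fully reproducible test bed for imputation × GRN interactions, and at
analysts who want to score their own (externally imputed) matrices or
ranked edge lists against a reference network.

## The evaluation model

For a ranked candidate edge list, the **top-k network** keeps every edge
whose competition rank is ≤ k, where k is the number of positive edges in
the evaluation network (tied weights share ranks, so more than k edges may
be reported). With TP the true positives among those reports,

- **early precision** EP = |TP| / n_reported,
- **network density** d = numEdges / ((numGenes × numTFs) − numTFs),
- **early precision ratio** EPR = EP / d, so EPR = 1 is the random-predictor
  level on any dataset, and
- performance change under imputation is log2(EPR_imputed / EPR_unimputed),
  with 0 meaning no change and −1 a 50 % decline.

Around this core the package implements the supporting analyses: gene
selection by smooth pseudotime fits (top-N most variable genes plus
Bonferroni-significant TFs at p < 0.01), TP/FP/FN edge classification,
Jaccard similarity + hierarchical clustering + adjusted Rand index across
models, variance/ANOVA decomposition of log2 ratios into imputation and
GRN factors, correlation-class regressions before vs after imputation,
chain vs feed-forward-loop motif classification with TPR/FDR, and binomial
downsampling of counts for low-depth stress tests.

## Worked example

```r
library(scGRNimpact)

cfg <- SimulationConfig(nTfs = 8, nGenes = 60, nCells = 150,
                        effectSize = 2.5, seed = 11)
net <- sampleGroundTruth(cfg)
net
#> GroundTruthNetwork: 60 genes ( 8 TFs ), 112 directed edges

ds  <- normalizeCounts(simulateCounts(net, cfg))
sel <- selectGenes(ds, nTop = 50)
sel
#> GeneSelection: 50 HVGs + 8 significant TFs -> 52 genes (nTop = 50 , alpha = 0.01 )

# unimputed baseline, partial-correlation GRN method
noimp <- evaluateRanking(inferPartialCorrelation(ds, sel, lambda = 0.2),
                         net, sel)
noimp$metrics
#> ModelMetrics: EP = 0.3269  EPR = 1.308  density = 0.2500

# diffusion-imputed model on the same gene universe
imp  <- imputeDiffusion(ds, knn = 10, t = 3)
diff <- evaluateRanking(inferPartialCorrelation(imp, sel, lambda = 0.2),
                        net, sel)
diff$metrics
#> ModelMetrics: EP = 0.6000  EPR = 2.400  density = 0.2500

log2Ratio(diff$metrics@epr, noimp$metrics@epr)
#> [1] 0.8757544

classifyMotifs(edges(diff$topk), diff$harmonized$ref)
#> MotifClassification: TP = 2 FP = 3 FN = 0 unclassifiable = 13
#>   TPR = 1  FDR = 0.6
```

Reading the numbers: the unimputed partial-correlation model reaches
EPR ≈ 1.31 — about 31 % better than a random predictor on this simulated
dataset — and on this instance diffusion imputation raises it to 2.40
(log2 ratio ≈ +0.88). The motif table shows the imputed top-k network's
chain predictions: among triples whose backbone exists in the truth, all
true chains are recovered (TPR = 1) but 60 % of predicted chains are
actually feed-forward loops (FDR = 0.6) — the transitivity error that
correlation inflation promotes.

A full factorial experiment (datasets × imputations × GRN methods, with
persisted intermediates, log2-ratio tables, Jaccard/ARI and motif
summaries) is one call:

```r
cfgx <- experimentConfig(
    datasets = list(d1 = SimulationConfig(seed = 3)),
    imputations = c("noimp", "knn_aggregate", "diffusion", "shrinkage"),
    grnMethods = c("tree", "mi", "pcor"), nTop = 80, masterSeed = 1)
run <- runExperiment(cfgx, outdir = "run1")
rep <- reportExperiment("run1")
```

Externally produced matrices and rankings enter through
`loadExternalImputed()` (genes × cells CSV) and
`loadExternalRankedEdges()` (TSV with header `Gene1 Gene2 EdgeWeight`).

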