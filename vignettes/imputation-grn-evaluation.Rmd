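---
title: "Evaluating imputation effects on GRN reconstruction: models and methods"
author: "scGRNimpact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating imputation effects on GRN reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scGRNimpact)
```

# Scope and model

scGRNimpact studies a pipeline interaction: scRNA-seq imputation modifies
the gene–gene dependence structure of an expression matrix, and gene
regulatory network (GRN) inference reads edges off exactly that structure.
The package provides every stage needed to measure the interaction under
controlled conditions — a simulator with known regulatory truth,
imputation operators, GRN scorers, and the evaluation metrics — plus
import paths so that matrices imputed by external tools and externally
computed ranked edge lists can be dropped into the same evaluation.

The evaluation machinery is exact and conventional throughout:

* **Top-k network.** Candidate edges are ranked by weight in descending
  order with competition ("min") ranks, so tied weights share the
  smallest rank of their group. The top-k network keeps ranks ≤ k with
  k equal to the number of positive edges in the evaluation network;
  ties can push the number of reported edges above k, and the early
  precision denominator is the *reported* count, not k.
* **Direction conventions.** Undirected methods emit each scored pair as
  two opposing directed records sharing a rank. During harmonization both
  prediction and reference are restricted to the selected gene universe,
  only edges going out of TFs are kept, self-loops are dropped, and
  duplicate directed records collapse to the record with the better rank.
  A consequence is that a bidirectional pair survives as two counted
  edges only when both endpoints are TFs.
* **EP, density, EPR.** EP = |TP|/n_reported;
  density = numEdges/((numGenes × numTFs) − numTFs), the size of the
  TF-sourced edge universe without self-loops; EPR = EP/density.
  Dividing by the density of each evaluation network makes EPR = 1 the
  random-predictor level on every dataset, which the test suite verifies
  both by Monte-Carlo calibration and by brute-force enumeration of all
  rankings on toy instances (the oracle ranking attains exactly
  1/density, the maximum).
* **Log2 ratios.** Performance change under imputation is
  log2(EPR_imputed/EPR_unimputed); the identity operator is the mandatory
  baseline and yields exactly 0.

# The synthetic-data generator

The simulator supplies what public benchmarks take from curated
references: a known, directed TF → gene truth and expression data whose
dependence structure follows it.

* **Topology.** Per-gene in-degrees are Poisson with mean `edgesPerGene`
  (default 2); regulators are drawn with probability proportional to a
  log-normal per-TF propensity, which produces hub TFs and a heavy-tailed
  out-degree distribution. At least one TF→TF and one TF→non-TF edge are
  guaranteed, because the evaluation conventions treat the two species
  differently.
* **Programs.** TFs follow smooth pseudotime programs — a 30/70 mix of
  sigmoids and Gaussian pulses with random centres and widths. Pulses
  dominate deliberately: monotone programs all correlate with one another
  through pseudotime itself, which would blur the contrast between
  regulated pairs and random pairs that the evaluation depends on.
* **Regulation.** A target's latent log-rate adds a saturating
  (tanh) transform of the weighted sum of its regulators' standardized
  activities; weights have magnitude `effectSize` and random sign.
  `effectSize = 0` disconnects the truth from the data, the null used to
  check that inference then scores at EPR ≈ 1.
* **Noise model.** Counts are gamma-Poisson (negative binomial,
  variance μ + φμ²; default φ = 0.3) around the latent rate scaled by a
  log-normal library size (sdlog 0.3, so normalization is non-trivial).
  Excess zeros are Bernoulli with probability exp(−μ/`dropoutStrength`):
  mean-dependent, vanishing for well-expressed genes, and disabled at
  strength 0. We parameterize dropout so that *larger* strength means
  *more* dropout and the zero-inflation disappears smoothly in the
  0-limit; low-mean entries are hit hardest, which is the behaviour
  imputation methods are designed around. A small latent log-normal
  jitter (sd 0.2) represents cell-level biological variability beyond
  pseudotime and keeps latent rates non-degenerate even for unregulated
  genes.
* **Latent layer.** The library-size-free latent rates are stored as an
  assay, because regulatory covariance claims are cleanest there: the
  raw-count layer adds depth variation and sampling noise that are the
  *subject* of imputation, not of the truth.
* **Downsampling.** `downsampleCounts()` is exact binomial thinning per
  entry; fraction 0.6 emulates reducing an experiment to 60 % of its
  sequencing depth. It is elementwise dominated by the input and is
  bit-reproducible under a seed.

What the generator does *not* emulate: transcriptional bursting kinetics,
batch structure, doublets, or the moment structure of any specific real
dataset. Passing tests therefore demonstrate correctness of the machinery
and qualitative reproducibility of the correlation-inflation phenomena on
controlled data — not quantitative claims about any particular tissue.

# Preprocessing and gene selection

Normalization scales every cell to the median library size and applies
log1p; all-zero cells are an error because they carry no information and
break the scaling. Gene selection follows the benchmark convention: the
top-N most variable genes across pseudotime plus all significantly varying
TFs (Bonferroni-corrected p < 0.01, correction over the tested TFs only),
with the same selected universe applied to every imputation layer so that
models are compared on identical footing.

"Variable across pseudotime" is operationalized as the deviance explained
by a smooth fit of expression on pseudotime. For the smooth we use a
fixed-knot natural cubic spline basis (df = 5) with an exact F-test
against the intercept-only model, rather than a penalized smoother with
data-driven degrees of freedom. The reason is calibration: the F-test's
null p-values are exactly uniform, which the suite verifies by simulation
(KS test over 1000 null genes), and family-wise control of the TF test is
then a clean Bonferroni guarantee. Penalized smoothers give approximate
p-values whose null distribution is not exactly uniform; for ranking HVGs
the two choices are nearly equivalent, but for the significance gate the
exact test is preferable. Constant genes return deviance 0 and p = 1 by
convention.

# Imputation operators

The three operators are deliberately light *stand-ins* named by mechanism,
not reimplementations of published tools; externally imputed matrices are
the fidelity route and enter via `loadExternalImputed()`.

* **kNN aggregation** (raw counts): stepwise neighbourhood doubling;
  at step s each cell's raw counts are summed over its min(2^s, k)+1
  nearest cells, distances measured on square-root-transformed,
  depth-scaled aggregates of the previous step, and the final aggregate is
  rescaled to the cell's original depth. k = 0 is the identity.
* **Diffusion** (normalized log scale): adaptive Gaussian kernel on the
  top principal components (bandwidth = distance to the knn-th
  neighbour), symmetrized — which also reconnects one-way kNN
  components — row-normalized to a Markov matrix M, output = expr · (Mᵗ)ᵀ.
  t = 0 is the identity; large t drives each gene to a stationary-weighted
  mean.
* **Shrinkage** (raw counts + size factors): gamma-Poisson posterior mean
  (count + a·μ)/(size_factor + a) with prior strength a and predicted
  mean μ from a cross-gene ridge regression of each gene on all others.
  The per-gene regressions are solved jointly through the partitioned
  inverse of X'X + λI (β_g = −B[−g,g]/B[gg]), one matrix inverse for all
  genes. a → 0 recovers normalized counts, a → ∞ the predictions.

Each family operates on its native substrate (aggregation on raw counts,
diffusion on log-normalized data, shrinkage on raw counts with size
factors). The suite checks the family-level qualitative contrasts that
motivate the benchmark: smoothing operators reduce null-gene variance
monotonically, diffusion inflates true-edge correlations, and shrinkage
introduces fewer spurious correlations than diffusion on independent
genes.

# GRN scoring methods

Four families mirror the usual benchmark selection:

* **tree** — per-target random-forest regressions on all TF expressions
  (impurity importance; the target is excluded from its own predictors).
  Importances are divided by the target's variance before pooling so
  high-variance targets do not dominate the global ranking.
* **boost** — the same contract with gradient-boosted trees and early
  stopping on a 20 % validation fold; gain importances, variance-scaled.
* **mi** — equal-frequency discretization (8 bins default), plug-in
  mutual information in bits for every TF–gene pair, and per-gene context
  normalization: the weight is the mean of the pair's z-scores within its
  two genes' MI distributions. This is an MI surrogate for
  partial-information-decomposition scoring, documented as such; genuine
  PIDC output can be imported as a ranked edge list.
* **pcor** — Gaussian partial correlations from the (optionally
  shrunk) precision matrix; pairs with |pcor| strictly above the 0.1
  threshold are kept, the absolute value being the weight. Singular
  covariances are an explicit error directing the user to shrinkage
  (`lambda > 0` mixes the correlation matrix toward the identity).

Undirected methods (mi, pcor) emit both directions at one shared rank;
harmonization then applies the TF filter. Tree and boosting methods are
deterministic under their seed; per-target seeds are derived from the
method seed and the target name.

# Structure, variance and motif analyses

* **Network similarity**: Jaccard index over the top-500 interactions per
  model, average-linkage clustering on 1 − Jaccard, and cluster purity as
  the adjusted Rand index against either the imputation or the GRN label.
  The clustering cut equals the number of levels of the annotation being
  scored.
* **Variance decomposition**: per dataset, the variance of log2 EPR
  ratios across imputations at fixed GRN method and vice versa, compared
  by a two-sided Wilcoxon rank-sum test; plus a per-dataset two-way ANOVA
  of the ratios on both factors. The ANOVA uses sequential (type-I) sums
  of squares with factor order (GRN, imputation) — the conservative order
  for the question "does imputation explain variance beyond the GRN
  factor"; with a complete balanced grid the order has no effect on the
  conclusions, and the table reports both factors in one pass.
* **Rank shifts**: for each TP edge of the unimputed top-k, its rank in
  the imputed full ranking; edges that the imputed model does not report
  at all receive the sentinel rank (universe size + 1) and are flagged
  rather than silently mixed in.
* **Correlation-class regression**: per classified edge, the absolute
  Pearson correlation before and after imputation, with one OLS line per
  class (TP/FP/FN). Absolute values are used on *both* axes: signed
  after-correlations make per-class lines ill-defined when imputation
  flips correlation signs, and the class contrast of interest is in
  magnitudes. Edges touching a constant gene are flagged and excluded, as
  are classes with fewer than two usable edges.
* **Motifs**: chains (X→Y→Z without X→Z) versus feed-forward loops (with
  X→Z), enumerated over ordered triples by an adjacency scan that the
  suite checks against an exhaustive O(n³) oracle. Classification follows
  the chain confusion scheme: TP = chain in both networks; FP = predicted
  chain that is a loop in the reference; FN = predicted loop that is a
  chain in the reference. Motifs whose backbone edges are absent from the
  reference are *unclassifiable* and reported as a separate count —
  folding them into FP would bias the FDR. Agreeing loops are likewise
  counted separately. Zero-denominator TPR/FDR are reported as missing,
  not as 0.

# Orchestration and reproducibility

`runExperiment()` executes the factorial grid, persists every ranked edge
list, metric row, similarity matrix and motif table as plain CSV/TSV, and
writes a JSON manifest of all parameters and seeds. Per-cell seeds are
derived deterministically from the master seed and the cell's labels, so
extending the grid never perturbs existing cells; a rerun under the same
master seed is byte-identical. `reportExperiment()` rebuilds every summary
from the persisted artifacts alone. Failed cells are recorded with their
error message in the metrics table and excluded from downstream summaries
— never silently dropped. The package exposes its functionality as R
functions; scripted runs are a few lines of Rscript around
`runExperiment()`.

# Numerical choices and degenerate inputs

* Ties in edge weights share competition ranks everywhere; ranking is a
  pure function of the weights, invariant to input row order.
* Constant genes: trend test returns (0, 1); MI is 0 by convention; tree
  and boosting weights into a constant target are 0; correlations
  involving a constant gene are flagged NA.
* Jaccard of two empty sets is 1 by convention, with a warning.
* log2 ratios require strictly positive metrics; EP with zero reported
  edges and EPR on an empty harmonized reference are errors, not NaNs.
* The simulator's problem sizes used in the test and acceptance suites
  (50–100 genes, 8–10 TFs, 120–200 cells, 10–1000 replicates depending on
  the statistic) were chosen to make each statistical check decisive at
  its stated level while keeping a full run in the minutes range on one
  core.

# Known limitations

* The imputation operators demonstrate family-level mechanisms; no claim
  of numerical equivalence to any published tool is made, and
  autoencoder-based imputation is out of scope entirely.
* The MI scorer is a context-normalized surrogate, not a true partial
  information decomposition.
* Pseudotime is taken as given (the simulator provides it); inferring it
  is out of scope, and real-data pseudotime error would propagate into
  the selection stage in ways the simulator does not model.
* Whether k should be computed before or after the TF-pair deduplication
  of the reference is a convention choice; we compute it after full
  harmonization, and both counts are visible in the harmonization result.
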