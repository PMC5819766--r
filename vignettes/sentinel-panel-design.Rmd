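---
title: "Designing sentinel gene panels: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sentinel gene panels: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentinelpanel)
```

## The problem

Whole-transcriptome profiling is too expensive for large screening
campaigns, but transcription is highly redundant: genes move in co-expressed
modules, so a small, well-chosen *sentinel* subset carries most of the
information of the full transcriptome. Panel design is then two coupled
problems — *which* genes to measure, and *how* to reconstruct the genes not
measured. This package solves both on the universal currency of
differential expression: a log2 fold-change matrix, genes × comparisons,
where each comparison is a treatment-vs-control contrast and comparisons
from the same study share a study label.

## Importance scoring

**Diversity (DIS).** Responses differ wildly across biological conditions;
a panel should contain the genes that drive the dominant expression
programs in *each* regime, not just globally. We therefore first reduce the
matrix by an uncentered SVD to `G` eigengenes, `G` minimal so that the
leading components capture a `var_fraction` (default 0.9) of total
variance, then k-means-cluster the comparisons (Euclidean distance on
their component coordinates, `k = 10` by default, k-means++ seeding with
ten restarts). Within each cluster the components are recomputed and each
gene is scored by the sum of its squared loadings on the first `G`
components; because loading columns are orthonormal, the scores of all
genes in a cluster sum exactly to `min(G, rank)` — a conservation law the
tests exploit. Per-cluster scores are summarised by the Tukey biweight
mean, a robust location estimate that down-weights clusters where a gene
behaves atypically.

Fold changes are differential contrasts already, so the PCA is uncentered
by default ("variance" = squared singular value); a `center = "gene-mean"`
switch is provided for corpora with systematic per-gene offsets.

**Co-expression (CIS).** A sentinel is useful in proportion to how well it
predicts its neighbours. Studies are randomly partitioned into `n_folds`
folds (default 20, whole studies never straddle folds — correlations
estimated within a study would otherwise leak into multiple folds), and
within each fold genes are clustered by average-linkage hierarchical
clustering under the distance `1 − |r|`, cut at height `h = 0.9`. The
absolute value deliberately groups anti-correlated partners: either one
predicts the other. A gene's fold-wise score is its mean squared
correlation with cluster-mates (0 for singletons, including zero-variance
genes, whose correlation is undefined); fold scores are biweight-averaged.
The default `h = 0.9` keeps the singleton fraction low; cutting much lower
dissolves genuine modules into singletons.

**Overall (OIS).** DIS and CIS are ranked from smallest to largest (rank
`N` = best; ties broken by ascending gene identifier so ranks stay a
permutation of `1..N`) and combined as the root-mean-square of the two
ranks scaled by `N`:

$$\mathrm{OIS}(g) = \frac{1}{N}\sqrt{\tfrac12\left(\mathrm{rank}_{CIS}(g)^2
  + \mathrm{rank}_{DIS}(g)^2\right)} \in (0, 1],$$

equal to 1 exactly when a gene tops both rankings. Rank combination makes
the two scores commensurable without calibrating their very different
scales.

**Tukey biweight.** The estimator iterates bisquare-weighted means from the
median with fixed scale `s = MAD + 10^{-4}\,\mathrm{median}(|x|)` and
tuning constant `c = 5` (the Affymetrix convention); observations more than
`c·s` from the current estimate get zero weight. Constant vectors return
the constant; singletons return themselves; a zero-spread guard returns
the median.

## Pathway-coverage refinement

Top-OIS selection concentrates on large co-expression modules and can leave
entire pathways unrepresented. Refinement repairs this with a greedy,
size-preserving swap loop over a GMT collection: while any pathway has
fewer than `q` selected genes (default 3), swap in the unselected gene
belonging to the most uncovered pathways and swap out the selected gene
with the fewest pathway memberships and lowest OIS. Three deliberate
choices make this loop safe:

- *Attainability cap*: a pathway with fewer than `q` members inside the
  scoring universe counts as covered once all attainable members are
  selected — otherwise the loop could never terminate.
- *Exclusion safety*: a gene whose removal would drop any pathway below its
  attainable level is ineligible for exclusion, and removability is judged
  with the incoming gene already added (which is itself protected for that
  iteration). Every swap therefore strictly increases the coverage count
  of some uncovered pathway, which bounds the iteration count and
  guarantees termination.
- *Determinism*: all ties break by (primary criterion, OIS, gene
  identifier), so refinement is a pure function of its inputs.

When no eligible swap remains, the partial result is returned with the
residual uncovered list attached — full coverage at a fixed panel size is
not always feasible, and the caller should see that rather than an
infinite loop. Nominated genes are merged afterwards as a pure union, so
panel growth from nomination never disturbs the refined core.

## Extrapolation by principal component regression

Given a training matrix and the panel, the sentinel submatrix is
decomposed by (uncentered) SVD and the first `K` components retained,
`K` the largest index with eigenvalue ratio
`λ_K / λ_1 ≥ lambda` (default 0.01). Each non-sentinel gene is regressed on
the `K` component coordinates — orthogonal regressors, so ordinary least
squares is exact, cheap, and needs no per-gene regularisation; the `lambda`
cutoff is what prevents overfitting to near-null directions. The composed
operator

$$A = B\,U_K^{\top} \quad (t \times s)$$

maps any new sentinel profile to predicted target fold changes in one
multiplication, is linear and homogeneous (zero in, zero out), and is
stored explicitly in the model together with its factors, which the tests
check for mutual consistency. With `center = "gene-mean"` the gene means
are removed for fitting and restored on application.

## Evaluation

Gene-level agreement between measured and extrapolated matrices pools all
(gene, comparison) entries: Pearson correlation; concordance rate — the
fraction of entries whose changed/unchanged status agrees, with "changed"
meaning `|log2FC| ≥ fc_threshold` (default 1.0, i.e. two-fold; most entries
are null, which is why even weak panels score high on concordance);
significance overlap — the fraction shared between the two top-1%-by-|value|
entry sets (ceiling size, index tie-break); and MSE.

Pathway-level evaluation ranks each comparison's genes by fold change
(ties by identifier) and walks the weighted Kolmogorov–Smirnov running sum:
hits add `|fc|^p` normalised by total hit mass (default `p = 1`; `p = 0`
recovers the classic unweighted KS statistic, which the tests verify
exhaustively against a brute-force oracle), misses subtract
`1/(N − N_{hit})`, and the enrichment score is the extreme deviation,
in [−1, 1]. Significance is an asymptotic two-sample KS test of in-set vs
out-of-set fold changes; differential pathways require `|ES| > 0.5` and
`p < 0.001`, and truth-vs-predicted call sets are summarised by recall and
precision. The same four agreement metrics are then applied to the
pathway × comparison ES matrices, with the concordance cutoff on the ES
scale (0.5).

Cross-validation partitions *studies* into folds, reselects the panel and
refits extrapolation on the retained folds each time, reconstructs the
held-out fold from its sentinel rows, and reports per-fold metrics with
mean/min/max summaries. Pooled (rather than per-comparison-averaged)
metrics are the default; this is one of several places where a reasonable
alternative exists, and the choice is exposed through the configuration.

## The synthetic corpus

The generator emulates exactly the structure the scoring steps assume:
fold changes are `Λ F' + ε`, with module genes loading on one latent
eigengene factor each (magnitudes uniform on [0.5, 1.5] with random signs,
so absolute-correlation clustering is genuinely exercised), non-module
genes pure Gaussian noise, and per-study lognormal intensity multipliers
creating the between-study heterogeneity that experiment clustering looks
for. Pathway collections are sampled to overlap modules with a tunable
alignment probability. It does **not** emulate probe-level microarray
physics, count noise, batch artefacts, or non-linear regulation — passing
tests demonstrate correctness of the algorithms under the model's own
assumptions, not performance on any real corpus.

Default generator conditions (500 genes, 200 comparisons, 40 studies, five
30-gene modules, `noise_sd = 0.1`, alignment 0.7) mirror a small but
realistically structured design corpus; individual analyses in the test
suite and the acceptance script state their own sizes, chosen so each
property has room to express itself:

- Module-recovery checks use 5 × 30 module genes plus 300 noise genes over
  100 comparisons in 20 studies — enough folds and comparisons for stable
  within-fold correlations.
- The designed-vs-random comparison uses 20 modules of 9 genes (latent
  rank 20) plus 100 noise genes with a 36-gene panel. This regime is
  chosen deliberately: when the latent rank is far below the panel size,
  *any* random panel spans the response space and extrapolates as well as
  a designed one, and the comparison degenerates (the corresponding
  full-corpus observation is that random panels match designed ones at the
  gene level). The advantage of importance scoring plus coverage
  refinement appears precisely when the panel budget is tight relative to
  the transcriptome's effective dimensionality, which is the regime real
  panels operate in.
- Exact-recovery checks use noiseless rank-K corpora with two sentinels
  per module, where principal component regression must reproduce held-out
  fold changes to numerical precision.

## Numerical and degenerate-input policy

Missing values are rejected at I/O time, never imputed. Zero-variance
genes become clustering singletons (CIS 0). Single-comparison experiment
clusters cannot yield a within-cluster PCA and are skipped with a warning;
folds with fewer than three comparisons are likewise skipped in CIS.
All-zero matrices raise degenerate-input errors rather than returning
NaNs. Rank decisions use a relative singular-value tolerance of 1e-10;
orthonormality and conservation identities are asserted at 1e-8. Every
stochastic step (k-means, study partition, simulation) takes an explicit
seed and restores the caller's RNG state, making all pipeline outputs
bit-reproducible; ties anywhere resolve by gene identifier.

## Known limitations

- Gene identifiers are opaque case-sensitive strings; probe-to-gene
  collapsing beyond a simple mean-by-map utility, and cross-platform
  identifier mapping, are out of scope.
- The refinement heuristic is greedy, not an optimal set cover; on
  adversarial instances it can stop short of a feasible cover (it then
  says so). Exhaustive small-instance testing shows this is rare.
- Enrichment p-values are asymptotic KS tests without multiplicity
  correction, matching the thresholds used for differential-pathway calls;
  normalised enrichment scores and permutation nulls are not provided.
- The hierarchical clustering step materialises a gene × gene correlation
  matrix per fold, which bounds practical universe sizes to a few tens of
  thousands of genes.
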