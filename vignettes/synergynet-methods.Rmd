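---
title: "SynergyNet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SynergyNet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynergyNet)
```

## The problem

Tumors driven by redundant and compensatory signaling rarely respond
durably to single agents, and high-order combinations (three or more
drugs) cannot be screened exhaustively: a pool of just seven drugs already
yields 120 distinct subsets of size two or more. SynergyNet implements an
in-silico triage strategy: learn a mapping from (cell line, drug) to
monotherapy potency from a large screen, then exploit the fact that a drug
is represented only through its target fingerprint to score *drug sets*
that were never screened, ranking them per cell line. Wet-lab
confirmation of the top candidates is then handled by the package's
dose-response synergy lab.

## Feature space

A modeling sample is the concatenation of two blocks whose layout is
pinned by a `FeatureSchema`:

* an **expression block**: the cell line's log-scale expression over a
  cancer-pathway gene panel (the panel restriction exists to avoid the
  curse of dimensionality; in the reference setting it has 215 genes);
* a **target block**: a binary fingerprint over a fixed target universe
  (1,093 targets in the reference setting), with 1 at every target hit by
  the drug.

A combination is encoded as the element-wise OR (set union) of its
members' fingerprints, with the expression block unchanged. This is the
only construction under which a monotherapy-trained model can score a
combination at all, and it makes a sham "combination" of a drug with
itself encode identically to the drug — a property the test suite pins
down. Labels are the natural log of IC50 in micromolar for regression
(`label_scale` also supports `log10_nM` and `raw`), and a thresholded
binary label for classification. The 10 nM positive-class cutoff is an
unusually strict potency bar, so both the threshold value and its unit
are configuration, not constants.

All feature columns are standardized (zero-centered, unit population
standard deviation) using statistics of the training split only; test
data never contribute to the statistics. The binary target block is
standardized along with the expression block — centering binary columns
is deliberate, since the two blocks otherwise live on incomparable
scales. Constant columns are flagged and mapped to exactly 0. Splits use
round-half-up on the training count, so 201,405 samples at 80% give
exactly 161,124/40,281.

## Predictors

The core model is a fully connected feed-forward network written in plain
R matrix algebra: ReLU hidden layers `y = ReLU(Wx + b)`, inverted dropout
after each hidden layer during training only, and a scalar head that is
linear for regression (MSE loss) or sigmoid for classification (mean
binary cross-entropy). Optimizers are Adam (regression default),
RMSprop (classification default) and plain SGD; weights start from seeded
Glorot-uniform draws and every source of randomness (initialization,
shuffling, dropout masks) flows through one integer seed, so a fixed seed
reproduces the loss history bit for bit. There is no early stopping and
no learning-rate schedule: epoch counts are fixed, as in the reference
configuration. The reference architecture (1308 inputs, hidden 200/100,
dropout 0.5) has exactly 282,001 trainable parameters; learning rates,
batch sizes and epochs default to 1e-5/128/200 (regression) and
1e-3/32/500 (classification).

Those defaults are tuned to screens with >10^5 samples. For desk-scale
worlds of a few hundred samples the package's pipeline
(`trainWorldModel()`) defaults to a smaller head — hidden 32/16, no
dropout, Adam at 1e-3, batch 8 — which trains in seconds and is what the
reproduction script uses.

Four classical baselines expose the same predict contract and are
interchangeable downstream: KNN (uniform weights; 6 neighbors for
regression, 5 for classification), random forest (200 trees/leaf 50
regression; 100/10 classification), RBF-kernel SVM (C=10, gamma=0.01
regression; C=1, gamma=0.1 classification) and gradient boosting (500
trees, minimum split 1000, rate 0.01, leaf 60 regression; 200/600/0.01/60
classification). The boosting backend maps minimum split/leaf sizes onto
`min_child_weight`, the closest regularizer in its implementation.
`gridSearchCV()` evaluates full Cartesian products under k-fold
cross-validation (seeded shuffle, contiguous blocks), with deterministic
first-in-product-order tie-breaks; the shipped default network grids have
level counts 5, 5, 3, 3, 5, 5 — a 5,625-configuration product.

## Metrics

Regression is scored by MSE, RMSE and R² (1 − SSE/SST around the mean of
the true labels), classification by sensitivity, specificity, accuracy
and Matthews correlation from the confusion table, plus AUC by
trapezoidal integration of the ROC curve. Metrics with zero denominators
come back flagged-undefined (`NA`), never silently 0, so aggregate tables
cannot average them away. The trapezoidal AUC equals the pairwise rank
statistic with half credit for ties; the tests verify this equivalence
against a brute-force oracle and against an independent implementation.

## Ranking

`enumerateCombinations()` emits every subset of a pool with sizes in a
requested band, each exactly once in canonical order; `2^n − n − 1` for
sizes 2..n, verified up to n = 12. `rankCombinations()` builds one
prediction sample per combination, scores them, and sorts ascending —
lower predicted pseudo-IC50 means a more potent combination. The
pseudo-IC50 is a rank score, not a concentration, and is never converted
back to dose units. Ties (which a continuous score essentially never
produces, but a degenerate model can) break deterministically by
canonical combination id. Singleton drugs can join the ranking universe,
giving 127 entries for a 7-drug pool.

## The synergy lab

Dose-response series are fitted with the median-effect model
`fa/fu = (D/Dm)^m` via least squares on the logit-log linearization;
`Dm` is the IC50. Fractions affected are clipped into [0.005, 0.995]
before the transform so 0%/100%-viability wells keep the regression
finite; dose series should bracket the IC50 within roughly ±3 doublings
to stay clear of the clipping bounds. Replicate wells are averaged per
dose *before* fitting, and fraction affected is 1 − viability/control
with control wells identified by zero dose. Mixed dose units in one
analysis are refused rather than converted silently.

Combination interaction uses the mutually-exclusive Chou–Talalay
combination index, the standard default for non-constant-ratio designs:
the combination is fitted as a single pseudo-agent over total dose, the
total dose achieving the requested effect level (default fa = 0.5, the
IC50 level — the effect level is exposed because reported CIs rarely
state it) is decomposed into per-drug doses by the molar-ratio shares,
and `CI = Σ d_i / Dx_i` with `Dx_i` the single-agent dose producing the
same effect. A sham combination gives CI = 1 *exactly*, which the tests
assert to 1e-9 — this identity is the strongest single check of a CI
implementation. Categories: CI < 0.3 strong synergy, 0.3 ≤ CI < 0.9
synergy, 0.9 ≤ CI ≤ 1.1 additive, CI > 1.1 antagonism. Ratio grids for
k = 2..5 drugs are the k+1 settings starting equimolar and then doubling
each drug's part in turn; `bestIC50()` takes the minimum across ratio
settings as a combination's best experimental result.

## Enrichment

`overrepresentation()` is a one-sided hypergeometric test of a query gene
set (typically the union of a combination's targets intersected with the
cell line's feature genes) against GMT gene-set collections, default
cutoff p < 0.01 on raw p-values; Benjamini–Hochberg adjustment is
available behind a flag since the default deliberately mirrors a
raw-cutoff reporting convention. One property worth stating because it is
easy to get backwards: with set, query and overlap fixed, *growing* the
background universe makes the overlap more surprising and so never raises
p.

## The synthetic world

`generateWorld()` builds a fully seeded toy world in which synergy *is*
complementary pathway coverage: genes and targets partition over
pathways, cell lines activate each pathway with probability 1/2,
pathway-member genes are shifted up by 2 log-units (noise sd 0.5,
baseline 6) where the pathway is active, and each drug draws 2–6 targets
from 1–3 pathways. The true potency of any drug set in any cell line is

```
log-IC50 = alpha − beta · nCov − gamma · max(nCov − 1, 0)
```

with `nCov` the number of distinct *active* pathways covered by the union
of targets, `alpha = 2` (ln µM; a ~7 µM baseline), `beta = 1.5` and
`gamma = 0.7`. Both terms count active covered pathways; the gamma bonus
is what makes complementary combinations strictly super-additive.
Monotherapy tables expose `exp(truth + N(0, σ²))` in micromolar;
combination truths are retained separately for evaluation. Plates draw
viability from the median-effect curve with `Dm = exp(truth)`, shared
slope 1.5, an 8-point two-fold dilution series containing Dm, optional
log-normal viability noise, and three replicates. The reference
configuration is 20 cell lines × 100 genes, 60 targets, 10 drugs and
σ = 0.1 — sized so the full train-rank-evaluate study runs in about a
minute on one CPU.

What the generator does *not* emulate: realistic transcriptomic
covariance, pharmacokinetics, dose scheduling, or partial/graded pathway
activity. Passing tests on this world demonstrate that the pipeline's
plumbing, encodings and statistics are correct and that the model
recovers a known signal; they do not certify performance on real screens.

## Known limitations

The union encoding carries a structural identifiability limit that shows
up clearly in the synthetic study: the ground truth counts *distinct*
covered pathways, but a monotherapy screen over a small drug pool (10
fingerprint patterns in the reference world) contains no direct evidence
about cross-drug overlap saturation. Any learner that extrapolates
near-additively is bounded by the additive-coverage ranking, and on the
reference world the mean per-cell-line Spearman correlation between
network-predicted and true combination rankings plateaus around 0.55–0.65
(the additive-coverage oracle itself reaches ≈ 0.77). Larger and more
diverse drug pools, which provide many overlapping fingerprints, are
exactly what the approach needs to learn saturation; this is worth
keeping in mind when reading the reproduction script's
`ranking_recovery_spearman` value.

Numerical conventions collected in one place: population (not sample)
standard deviation in the standardizer; round-half-up training-split
sizes; logit clipping bounds [0.005, 0.995]; CI category boundaries
closed on the additive side; duplicate expression rows collapsed by
arithmetic mean and duplicate response pairs by geometric mean (IC50s are
log-scale quantities); first-in-order tie-breaks in grid search and
best-IC50 selection; all RNG routed through explicit integer seeds.
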