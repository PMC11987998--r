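---
title: "A three-stage grid-search mechanism for low-budget DFNN tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-stage grid-search mechanism for low-budget DFNN tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threestage)
```

## The problem

Clinical teams who curate a tabular EHR-derived dataset — one row per
patient, integer-coded risk factors, a rare binary outcome such as
metastasis within a horizon — often want a deep feedforward network (DFNN)
risk model but have a hard compute budget. A DFNN has many tunable
hyperparameters; `threestage` models 13 of them: network depth (1–4 hidden
layers), hidden-layer width (1–1005 nodes), activation function, kernel
initializer, optimizer family, learning rate (0.001–0.3), momentum (0–0.9,
SGD only), iteration-based learning-rate decay (0–0.1), dropout rate
(0–0.5), epochs (5–2000), batch size (1 to the cohort size), and L1
(0–0.03) and L2 (0–0.2) weight penalties. Even a modest grid over these
dimensions explodes: with 4 depth options and 22 width options counted per
layer there are already `r format(structural_count(1:4, 22), big.mark = ",")`
network structures, and a full 13-dimensional grid of small per-dimension
value lists reaches ~4.3 × 10^14 settings — centuries of compute at any
realistic per-setting cost. The package implements a heuristic three-stage
mechanism that makes a *low-budget* grid search feasible, together with the
budget arithmetic, the result analytics and the Shapley-value explanation
machinery around it.

## The mechanism

Every candidate *setting* (one value per hyperparameter) is scored by
stratified 5-fold cross-validation on an 80% train–test split: five
networks are trained, each tested on the held-out fold, and the mean of
the five fold AUCs (`mean_test_auc`) is the setting's score. The held-back
20% validation set is never touched until a final top model is refit.

* **Stage 1 — one-hyperparameter-at-a-time sweeps.** Each dimension is
  swept over a wide value list while the others stay at a base setting.
  From each sweep the *proper values* are extracted: values whose score
  reaches the cycle mid-point `(0.5 + best)/2` — the search's own notion
  of a "decent" model. This prunes the extreme values that produce
  performance outliers while keeping the informative range.
* **Stage 2 — grid over the proper values.** Settings are evaluated in
  deterministic enumeration order up to a cap, and the mean running time
  per setting (RTPS) is estimated as a running mean. RTPS converts a time
  budget into an affordable setting count (`settings_for_budget()`) and
  back (`estimate_runtime()`).
* **Stage 3 — six refinement cycles.** Cycles c1–c3 are *sweet-spot grid
  searches* (SSGS): the candidate lists shrink to an index window of
  ±`radius` positions around the previous cycle's best value in each
  dimension. Cycles c4–c5 first apply *out-of-the-local-optimum* (OLO)
  reseeding — the best already-evaluated setting that escapes every
  previous neighborhood in at least one dimension — and then run an SSGS
  around the new center. Cycle c6 is a *randomized grid search* (RGS):
  settings drawn uniformly and independently per dimension from the full
  proper pool, de-duplicated by rejection, so every pool member has a
  chance of selection.

The expected signature, which the acceptance checks verify on synthetic
data, is that the best model comes from Stage 3, SSGS cycles have the
higher all-model averages and decent-model (CHS/TNS) ratios, and the RGS
cycle is competitive at the top but dragged down on average by the
randomness of its draws.

## The built-in DFNN trainer

No deep-learning framework is attached: the package carries a compact,
pure-R feedforward trainer that honors every searched dimension. Design
points worth knowing:

* **Output layer.** Two softmax nodes with cross-entropy loss; the
  positive-class score feeds the AUC.
* **Initializers.** Glorot/He normal and uniform use their standard
  variance scaling. `constant` initializes all weights at 0.1 — a
  deliberately poor, symmetric choice (all hidden units within a layer
  stay identical); the value 0.1 rather than 0 keeps the option trainable
  at all instead of freezing every gradient path.
* **Optimizers.** SGD (with momentum), Adagrad, Adam, Nadam and Adamax
  with conventional constants (β₁ = 0.9, β₂ = 0.999, ε = 1e-7). The
  iteration-based decay follows the classic schedule
  `lr_t = lr / (1 + decay · t)` over weight updates.
* **Dropout** is inverted dropout on hidden activations; derivatives are
  taken at the pre-dropout activations.
* **Standardization.** Predictors are centered/scaled inside training
  (constants stored in the model) — coded ordinals at very different
  scales otherwise destabilize the first layer.
* **Divergence policy.** A non-finite loss stops training, keeps the last
  finite weights, and the fold is recorded with AUC 0.5 plus a flag
  rather than aborting — Stage 1 deliberately probes extreme values, and
  one pathological setting must not kill a sweep.
* **Batch size** is clamped to the training-fold size.

## Numerical and procedural choices

* **Counting conventions.** A pool can count structures per layer
  (depth L contributes `widths^L`; reproduces the worked combinatorics
  exactly) or with one width shared by all layers (`"uniform"`), which is
  what the staged search itself uses — the two structural dimensions act
  as one 2-D "mstruct" hyperparameter there. Cardinalities are computed
  in exact arithmetic and returned as decimal strings beyond 2^53.
* **Budget arithmetic** uses 365-day years (31,536,000 s) for
  extrapolations, and `settings_for_budget()` adds a 1e-9 epsilon before
  flooring so the estimate/invert round-trip is exact under floating
  point.
* **Capped SSGS cycles** take settings nearest-first from the window
  center (L1 distance in candidate-index space, ties by enumeration
  order). A lexicographic prefix of the window would pin every later
  dimension at the window's low edge and never even evaluate the center;
  nearest-first is what a budget-capped neighborhood search means.
* **OLO details.** Exclusion is "outside in at least one dimension" —
  the weakest rule that guarantees escape from the exact prior window.
  Reseeding considers only evaluated settings whose values exist in the
  proper lists (otherwise no window could be formed around them); if
  nothing escapes, the run falls back to the previous cycle's best and
  proceeds.
* **Ties.** "Best" is the highest `mean_test_auc`, earliest evaluation
  order first. Records at exactly the mid-point count as decent.
* **Report rounding** is half-away-from-zero (`round_half_up()`), the
  convention of the printed tables this package's reports mirror; base
  R's half-to-even would shift 5-decimal values ending in 5.
* **Seeds.** One master seed per run; per-cycle, per-setting and per-fold
  seeds derive from it through a fixed hash of a text label, so the whole
  run is reproducible while no two trainings share a stream.

## Shapley explanation machinery

`exact_shapley()` evaluates the classical formula by full subset
enumeration (guarded at 20 features): a synthetic sample takes the case's
real values on the subset and per-feature *background values* elsewhere,
where backgrounds are the feature means of k-means centroids of the
training data (k = number of features, `kmeans_background()`). All 2^|F|
synthetic samples are scored in one model call. `sampled_shapley()` is the
unbiased permutation Monte-Carlo estimator of the same quantity;
`shapley_explain()` switches between them at 15 features. Efficiency,
symmetry and dummy hold exactly on the enumerated path and are tested on
constructed games, with the sampled path checked against the exact one.

Feature importance is the mean absolute attribution over test cases;
`dependence_analysis()` ranks the other features by Pearson correlation
with the top feature's attribution column. Pearson on coded values is a
pragmatic choice — the association measure is not otherwise pinned down —
and one caveat follows from it: when features are mutually independent
and the background equals a feature's mean, an interaction partner's
correlation with the driver's attributions vanishes by symmetry, so the
k-means background (which is generally *not* the column mean) is also
what makes partners detectable.

`hyperparameter_importance()` turns a grid-search log into a feature
table — kernel initializer recoded constant→0, glorot_normal→1,
glorot_uniform→2, he_normal→3, he_uniform→4; activation and optimizer
recoded alphabetically (flagged as a package convention; only the
initializer map is fixed externally); depth and width collapsed into a
single complexity scalar `mstruct` (total hidden-node count) — fits a
100-tree random-forest regressor of `mean_test_auc` on an 80% split, and
computes Shapley attributions of the held-out 20% against a k-means
background with k equal to the number of hyperparameter features.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws independent, uniformly distributed integer
codes per predictor and a Bernoulli outcome from a logistic model whose
intercept is calibrated by bisection to a target prevalence; effect sizes
are log-odds per level step. It reproduces the *shape* of the study's
cohorts (e.g. 4189 cases × 20 predictors at 437/4189 prevalence) and a
known planted signal, which is exactly what recovery tests need.
It does not emulate correlated risk factors, nonuniform level
frequencies, label noise beyond the logistic link, or any real cohort's
joint distribution — so passing tests demonstrate that the machinery
finds what was planted under its own assumptions, not that any clinical
result transfers.

## Problem sizes used in checks

The packaged demo study (`demo_dataset_config()`, `demo_search_config()`)
uses a 160-case, 6-predictor cohort (30% prevalence, two signal
predictors, Bayes AUC ≈ 0.81) and a schedule of roughly 110 settings per
run — Stage-1 sweeps over depth, width, initializer, optimizer, learning
rate, dropout and epochs; Stage 2 capped at 16 settings; five SSGS cycles
of 12; a 16-setting RGS — small enough that a full eight-cycle run takes
tens of seconds on one CPU while still exercising every cycle type. The
qualitative search properties are asserted as medians over 20 master
seeds. The study's absolute AUC tables are not reproducible at this
scale: they require the original cohorts and on the order of 10^6 model
trainings; the package reproduces their *arithmetic* (group averages,
mid-point statistics, RTPS/TNS/TRT accounting, relative improvements)
exactly from logged values instead.

## Known limitations

* The trainer is plain R: fine for desk-scale networks (thousands of
  parameters), not for the 1000-node widths of the full space; the
  search logic is agnostic to where records come from, and logs from any
  trainer can be analyzed and explained.
* Single-process execution; no distributed scheduler.
* No calibration or decision-curve metrics — discrimination (AUC) only,
  matching the mechanism being modeled.
* OLO exhaustion falls back rather than widening the search with new
  evaluations.
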