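---
title: "Heterogeneity-aware forests: model, simulator and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity-aware forests: model, simulator and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the package's methods are defined, which knobs
matter, what the synthetic cohort generator does and does not emulate, and
the numerical conventions adopted wherever a choice had to be made. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The regression forest

The base model is a random forest of un-pruned CART regression trees grown
on bootstrap samples. At every node a fresh subset of `mtry` features is
drawn without replacement from all `M` features, candidate thresholds are
the midpoints between consecutive distinct sorted values of each candidate
feature within the node (at most `k − 1` per feature for a node of size
`k`), and the split maximizing the reduction in the node's sum-of-squares
response cost is taken. A node is eligible for splitting while it holds at
least `n_size` samples; otherwise, or when every candidate feature is
constant within the node, it becomes a leaf.

Each leaf stores three things: the *distinct original* training-sample
indices of its members, the mean response, and the per-cancer-type sample
counts. The mean and the counts are computed with bootstrap multiplicity —
they describe the sample the tree was actually fitted on — while the member
set is de-duplicated because it feeds the nearest-neighbour weight view of
prediction, whose indicator runs over distinct training samples.

Defaults are `ntree = 100`, `mtry = 10`, `n_size = 4`: the standard working
point for expression-based drug-response panels of tens to low hundreds of
samples, and the configuration used throughout the package's own
experiments.

### Two aggregation rules

`forest_predict()` exposes both natural aggregations:

* `"weights"` (default): average the per-tree nearest-neighbour weights and
  apply them to the training responses — the formula-level definition of a
  forest prediction.
* `"leaf_mean"`: average the reached leaves' stored means.

The two coincide exactly when no leaf contains bootstrap duplicates (the
test suite asserts this with the `bootstrap = FALSE` hook) and differ only
through multiplicity otherwise: leaf means weight duplicated samples twice,
the weight form does not. HARF's prediction stage uses `"leaf_mean"` by
default because the vote-and-average arithmetic of the method is defined on
leaf means; a switch provides the pooled-weight variant. `kfold_cv()`
accepts `aggregate = "leaf_mean"`/`"weights"` to force one rule on every
method when exact A-vs-B comparability matters more than canonical
defaults.

### Determinism and tie-breaking

Reproducibility is a contract: the same seed yields the same forest,
regardless of growth order, because every tree draws its own child RNG
stream from the root seed. Split ties are resolved deterministically —
smallest feature index first, then smallest threshold. One subtlety is
worth recording: two different features can induce *exactly* the same
partition of a node (common in small or bootstrap-duplicated nodes), in
which case their gains are mathematically equal but the vectorised
cumulative-sum evaluation rounds them differently. The split search
therefore requires a challenger to beat the incumbent by a small
scale-relative epsilon (`1e-10` times the parent cost), which restores the
documented tie rule; gains differing by less than that are treated as ties.
The exhaustive-search oracle tests cover exactly this regime.

## HARF: vote, select, average

Every leaf knows its cancer-type composition, so a test sample routed down
the forest collects one leaf-majority type per tree. The modal vote is the
sample's inferred type; the response is the unweighted mean of the leaf
means of the trees that voted for it. Conventions:

* Leaf-majority ties and modal ties both go to the lowest category index.
* In the two-type case a `vote_threshold` t replaces the plain mode: the
  sample is assigned type 1 when its type-1 vote fraction is at least t.
  The boundary is inclusive so that t = 0.5 reproduces the plain mode
  *including* its tie rule; the threshold is only meaningful for two types
  (for K > 2 the plain mode is always used).
* The selected-tree set cannot be empty under the modal rule (the mode is
  voted by at least one tree). Under an off-centre threshold it can be;
  the implementation then falls back to all trees.
* With one cancer type, or all labels equal, every tree votes identically
  and HARF reduces bitwise to the plain forest under a matched aggregation
  rule — the test suite asserts this reduction exactly.

## The multivariate extension

For joint prediction of r drugs the node cost becomes the sum of squared
Mahalanobis distances to the node mean. Two estimation choices were
genuinely open:

* **Where to estimate the covariance.** Λ is estimated once per node being
  split (maximum likelihood, divide by k) and held fixed while scoring both
  children of every candidate split. Re-estimating inside each candidate
  child is ill-conditioned at realistic node sizes (children can be smaller
  than r) and makes gains non-comparable across splits; it remains
  available as `per_child = TRUE` for study.
* **Regularization.** A ridge of `1e-6 · trace(Λ)/r` (plus a tiny absolute
  floor) is added to the diagonal before inversion, so near-singular and
  constant-response nodes stay well defined. Nodes with fewer than two
  samples have cost 0 by convention — they are leaves under any sensible
  `n_size` anyway.

Internally the fixed-Λ cost is computed by whitening the node's responses
with the Cholesky factor of Λ⁻¹, which turns the Mahalanobis split search
into the ordinary sum-of-squares search in transformed coordinates. With a
single response this whitening is a positive scalar rescale that cannot
change the selected split, so it is skipped entirely — making the r = 1
multivariate fit reproduce the univariate fit bitwise, exact tie resolution
included.

Note one self-referential property: with Λ estimated from the same node and
no ridge, the node's own cost is identically `k · r`; the cost only becomes
informative when Λ is held fixed across a comparison, which is precisely
how the split search uses it.

## The vote-model theory

The idealized analysis treats the T per-tree votes as independent
Bernoulli trials with per-class accuracies `b0`, `b1` and a class-0 prior
C. The count of class-0 votes is then binomial under either truth, giving
a closed-form Bayes count threshold and Bayes error.

Conventions adopted:

* The classifier rule is *strict*: declare class 0 when the integer count k
  exceeds the (generally non-integer) threshold T̂; ties at an integer
  threshold go to class 1. `bayes_error()` is computed as
  `Σ_k min(C·P(k|0), (1−C)·P(k|1))`, which equals the two binomial tail
  sums around T̂ whenever T̂ is defined and remains well defined in the
  degenerate uninformative case (`b0 = b1 = 1/2`), where the threshold
  itself does not exist and the error is `min(C, 1−C)`.
* Deriving the threshold from the binomial likelihood-ratio gives
  `T̂ = T/2 + log((1−C)/C) / (2 log(b/(1−b)))` in the symmetric case
  `b0 = b1 = b > 1/2`: declaring the *rarer* class requires more than half
  the votes. A sign-flipped variant of this formula (suggesting the
  opposite shift) circulates; the package follows the direction that the
  brute-force posterior-crossover oracle confirms, and the corresponding
  test enumerates every T ≤ 15 crossing point.
* `estimate_tree_accuracies()` counts leaf-majority votes over
  (tree, sample) pairs on the training data by default, clipping the
  estimates into `[1/(2TS), 1 − 1/(2TS)]` so they always form a valid vote
  model. The in-bag tally is optimistically biased — a tree's leaf
  majorities echo its own bootstrap labels — so an out-of-bag variant
  (`oob = TRUE`) is provided and is what the shuffled-label null test uses.

The independence assumption is the theory's known weakness: real trees
share training data and features, so the empirical misclassification rate
plateaus with growing T instead of vanishing. The acceptance tests assert
only the direction (empirical rate at or above the theoretical floor,
non-increasing in T), not the curve's values.

## The synthetic cohort generator

The generator exists so that every stage — simulation, forest growth,
classification, evaluation, theory — is testable end to end without
external data. Each synthetic cell line is a parallel block of kinases: up
to `max_targets = 5` distinct targets drawn from a pool of
`n_targets_pool = 10`, with type 1 biased toward the low-index end of the
pool (half-normal distance from the bottom, floored to an index) and type 2
mirrored at the top. Sensitivity to a drug is the drug's weakest inhibition
over the cell line's kinases, scaled by a uniform cell-line potency b; a
cell line sharing no kinase with the drug is insensitive (0). Expression
starts from a per-gene beta(2, 2) base value scaled to [0, 10] and shared
across samples; ten marker genes are shifted up by N(1.25, 0.5²) in type-1
samples, the remaining genes are shifted down by the same law in type-2
samples (a disjoint ten-gene down-set and a no-down-set variant are
configurable), and every entry receives N(0, 0.4²) noise. The 0.5 and 0.4
are standard deviations.

Design notes:

* **Index mapping.** Mapping the continuous truncated-normal draws to pool
  indices by *flooring the distance from the favored end* keeps the anchor
  kinase (index 1 for type 1, index 10 for type 2) the single most likely
  target, which is the bias the construction is meant to encode; rounding
  would silently move the mode one step inward.
* **Potency calibration.** The default drug profile fully inhibits the
  low-index half of the pool (primary targets) and weakly (5/17) inhibits
  the high-index half, and the default potency is uniform on [0.7, 1]
  (mean 0.85). Together these place the two class mean sensitivities at
  0.85 and 0.25 — the canonical well-separated two-type study this package
  targets. A fully diffuse potency on [0, 1] is available
  (`potency_range = c(0, 1)`) but caps the attainable class mean at 0.5 and
  inflates the within-class response variance to the point where it, not
  the between-type gap, dominates cross-validated error; the heterogeneity
  effects the package demonstrates are then still present but no longer
  dominant. This calibration was fixed once, from the targeted class means,
  and is not a tuning surface.
* **What it does not emulate.** Real panels have correlated genes, batch
  structure, heavy-tailed and missing responses, more than two types, and
  type boundaries that are not encoded in every gene. Passing tests on
  these cohorts demonstrates the machinery's correctness and the direction
  of the heterogeneity effects under clean separation — not performance on
  real screens.

`make_dataset()` is a deterministic function of `(config, seed)`; the
optional `class_means` rescaling supports response-gap and imbalance
experiments by matching each type's sample mean to a requested value.

## Evaluation harness

Cross-validation is stratified by cancer type by default — per-type error
summaries from an integrated model are impossible if a fold lacks a type —
with a label-blind mode behind a flag. Pooled metrics are always computed
over the union of held-out predictions, never by averaging per-fold
metrics. Every experiment (per-type versus integrated forests, top-tree
selection, two-stage baselines, one-hot forests, vote-threshold sweeps) is
a deterministic function of `(data, seed)`.

Choices worth recording:

* **Top-tree selection** ranks trees per type by validation MAE (ties by
  tree index) and keeps the best half by default, evaluated on a held-out
  test split of a 60/20/20 stratified partition.
* **Two-stage baselines.** Both variants classify the test sample with an
  explicit classifier first — by default LDA on the ten genes with the
  largest between-type F statistic, since expression panels are wider than
  the sample count. Variant B pre-categorizes trees by their per-type
  validation MAE (forest grown on 75% of the training data, validated on
  the rest) and predicts with the classified type's trees; variant C keeps
  the leaf-majority tree selection and only outsources the type decision.
  The classifier is pluggable (`classifier_hook`), so a stronger or
  oracle classifier can be substituted in experiments.
* **One-hot forests** append one indicator column per type to the feature
  matrix; indicator columns constant across all samples are dropped, which
  makes the one-type case an exact identity with the plain forest.
* **Threshold sweeps** reuse the same folds and fitted forests across the
  whole threshold grid, so the curve isolates the decision rule.

## Problem sizes used by the tests

The packaged experiments run at the scale the methods are designed for:
cohorts of 25 + 25 (to 50 + 50) cell lines with 100 genes, forests of 100
trees, 3-fold cross-validation, 30 replicate cohorts for the per-type
versus integrated comparison and 20 replicates for the directional
experiments; the brute-force oracles run on nodes of at most 10 samples and
vote models of at most 15 trees, where exhaustive enumeration is exact.

## Known limitations

* Univariate response experiments assume the first response column in the
  tree-ranking and two-stage code paths; multivariate evaluation pools
  errors over all (sample, drug) entries without per-drug weighting.
* The vote theory is binary; for K > 2 only the plain modal rule is
  provided, and `estimate_tree_accuracies()` refuses non-binary models.
* Missing values are rejected at load time — imputation is out of scope.
* The forest is a regression ensemble throughout: no classification trees,
  pruning, boosting or feature-importance machinery.
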