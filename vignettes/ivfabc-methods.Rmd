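---
title: "Methods: hybrid LR-ABC feature selection for IVF outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid LR-ABC feature selection for IVF outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivfabc)
```

## Scope and data model

`ivfabc` predicts a binary embryo-transfer outcome from a fixed 22-predictor
schema: 20 binary supplement/lifestyle/clinical indicators, the oocyte
retrieval count, and age. The column order is part of the on-disk contract
because feature masks are index-based; `table2_features()` is the single
source of truth. Binary columns are strictly {0, 1} and missing values are
rejected rather than imputed — the upstream preprocessing that produces
these flags (active-ingredient binarization) defines every cell.

The binarization rule maps raw intake records to flags: an ingredient flag
is 1 exactly when the patient's total daily intake reaches 100% of the
ingredient's daily requirement. Totals are summed across all products per
patient before thresholding, which matches the "meets all daily needs"
semantics and makes the operator monotone (adding an intake record can
never clear a flag); a stricter per-product mode is retained behind a flag
for sensitivity analyses. Amount units must match the requirement table's
units exactly — no unit conversion is attempted.

## The synthetic cohort generator

The study data are private, so the generator is the package's test bed. It
reproduces the published marginal summary of the cohort:

* binary indicators: independent Bernoulli draws at the published
  prevalences (e.g. working status 0.72, omega-3 0.39, melatonin 0.006);
* age: normal(34.36, 4.58) truncated to [24, 43] by inverse-CDF sampling,
  then rounded to integer years (the published minima/maxima are integers);
* oocyte count: the published SD (9.81) far exceeds the mean (7.58), which
  rules out a Poisson model, so a negative binomial is truncated to
  [0, 58] and its (mu, size) solved by nested one-dimensional root
  searches so that the *post-truncation* mean and SD equal the published
  values. The truncated moments are computed exactly by summation over the
  support, so this calibration is deterministic and tolerance-free
  (`uniroot` at 1e-9/1e-10).

Outcomes are drawn from `Bernoulli(plogis(beta0 + Xs %*% beta))`, where
`Xs` standardizes each predictor by its *specification* moments (binary:
`(x - p)/sqrt(p(1-p))`). Coefficients therefore act on a comparable scale
across binary and count features: `beta = 2` is a two-SD effect whether it
sits on a rare supplement or on the oocyte count. When no intercept is
given it is calibrated so the marginal outcome prevalence hits a target
(default 0.38): closed form `qlogis(target)` for a null signal, otherwise
a bracketed root search on a 100,000-draw Monte-Carlo estimate of
`E[plogis(beta0 + Xs beta)]`, deterministic for a fixed seed.

Features are independent by default because the published summary gives
only marginals. A Gaussian-copula hook accepts a correlation matrix for
dependence studies but is off by default. What the generator does *not*
emulate: real between-feature dependence (supplement co-prescription,
age-oocyte correlation), dose/duration/adherence structure, and any
nonlinear outcome mechanism. Tests passing on synthetic cohorts therefore
demonstrate algorithmic correctness — leakage-safety, selection recovery,
calibration of the test statistics — not clinical validity on real data.

## The ABC optimizer

The artificial bee colony is the canonical formulation: employed bees
perturb each food source in one uniformly chosen coordinate against a
uniformly chosen partner, `v_ij = x_ij + phi (x_ij - x_kj)` with
`phi ~ U(-1, 1)`, clipped to the box; greedy selection keeps the better of
source and candidate and resets the trial counter on improvement;
onlookers re-sample sources with fitness-proportional probabilities
(`n_sources` selections per iteration); at most one scout per iteration
replaces the worst over-limit source. The fitness transform is
`1/(1 + f)` for `f >= 0` and `1 + |f|` otherwise. Elitist global-best
tracking is on by default, which guarantees a monotone non-increasing
best-so-far trajectory.

Tunable parameters and defaults:

| parameter | default | rationale |
|---|---|---|
| `n_sources` | 15 | study setting; read as 15 food sources with 15 onlooker selections |
| `max_iterations` | 30 | study setting |
| `abandonment` | 0.01 | study setting, interpreted as a fraction of the evaluation budget |
| trial limit | `max(1, round(0.01 * 15 * 30)) = 5` | a raw limit of 0.01 trials is meaningless for an integer counter; an explicit integer override exists |
| decode threshold | 0.5 | mask bit is 1 iff the coordinate is `>= 0.5` (closed lower boundary, the documented tie rule) |

The rounding in the trial limit is half-up (`floor(x + 0.5)`), not R's
banker's rounding, so `4.5` yields 5. The evaluation budget is bounded by
`n_sources * (2 * max_iterations + 1)` plus one evaluation per scout
replacement, and the implementation counts calls so the bound is
assertable.

For feature selection the search space is `[0, 1]^p` decoded to binary
masks. An all-zero mask cannot be fitted; it receives the largest finite
double as a sentinel objective, is never selected by onlookers against any
real value, and is quickly abandoned. The wrapper objective is
`1 - mean` inner stratified k-fold score of the base learner on the masked
features, with SMOTE applied inside inner training folds. Inner folds are
drawn once per search so every mask is compared on identical splits, and
objectives are memoized by mask key — single-coordinate moves frequently
leave the decoded mask unchanged, and in practice the cache absorbs
roughly three quarters of evaluations. Inner `k = 3` rather than 5: the
search performs ~900 evaluations, and tripling each one's cost buys no
measurable ranking benefit at these cohort sizes. A fold score whose
metric is undefined (e.g. precision with no positive predictions) counts
as 0 — the worst value — so degenerate masks are penalized rather than
silently skipped.

Whether the search should cover all p features or only the L1-selected
subset was genuinely open; the default searches the full space, with the
L1 mask warm-starting one initial food source (so the stage-2 solution is
always reachable). An alternative continuous mode — optimizing coefficients
directly against a CV objective — can be assembled from
`abc_optimize()` on a continuous space, but binary mask search is the
default because it matches the three-stage model naming and report
structure.

## Model stages and base learners

Stage 1 fits the base learner on all features; stage 2 applies lasso
(L1-logistic, `glmnet` at a fixed penalty, internally standardized)
selection then fits; stage 3 runs the ABC mask search. All stages honour
one contract: `predict()` takes the full original feature set and applies
the stored mask internally, so a fitted model cannot be fed pre-masked
data inconsistently. An empty lasso mask at extreme penalties is returned
flagged infeasible; stage 2 falls back to all features with a warning.

Base learners are the standard library implementations (`class::knn`,
`rpart`, `e1071::svm`, `randomForest`) with deliberately few knobs:
knn `k = 5`; CART `cp = 0.01`, internal cross-validation disabled
(`xval = 0`; it is unused and would consume RNG); SVM radial, `cost = 1`,
features standardized by training moments; RF `ntree = 100`. One hundred
trees rather than the library's 500 is the package default because the
wrapper search refits the learner ~1,500 times per outer fold at cohort
sizes in the low hundreds, where 100 trees already stabilize the
out-of-bag ranking; the value is a `base_params` override away and is
recorded in the run manifest.

SVM probabilities come from a logistic link fitted on the training-set
decision values (the decision-value sign is normalized against the level
order first). This keeps every learner probability-capable — so Brier,
calibration and AUCs are computable for all 12 grid models — and keeps
fixed-seed runs byte-reproducible, which libsvm's internal Platt
cross-validation (driven by a non-R RNG) would not.

Class labels use the 0.5 probability threshold throughout.

## Evaluation harness

`stratified_folds()` shuffles within class and deals counts so per-fold
class totals differ from proportionality by at most one; class remainders
go to the folds with the smallest running totals, so overall sizes are
balanced too (162 cases with 63 positives at k = 5 give sizes
33/33/32/32/32 and positives 13/13/13/12/12). `k = n` is the leave-one-out
boundary: singleton folds, stratification vacuous — the general
pre-condition (every class count at least k) cannot hold there and the
case is special-cased rather than rejected.

SMOTE balances classes exactly by interpolating
`s = x_i + u (x_j - x_i)`, `u ~ U(0, 1)`, between a minority row and one
of its `k = 5` minority nearest neighbors (shrunk with a warning for tiny
minorities; a singleton minority is an error). Inside `cross_validate()`
resampling happens strictly after the split and only on the training
portion; synthetic rows carry no original row index, and the report's
audit field counts (and tests assert) zero overlap between training ids
and test indices. The deliberately wrong protocol — SMOTE before
splitting — exists only in the test harness, where it demonstrably inflates
accuracy on label-permuted data.

Metrics follow the standard confusion-matrix forms: accuracy
`(TP+TN)/total`, sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`,
F1 `2PR/(P+R)`. A zero denominator yields `NA` with a reason code, never a
silent 0, and `NA` folds are excluded from averages with an exclusion
count. Both fold-averaged and pooled-count views are first-class outputs
because the two conventions genuinely disagree on small folds. ROC-AUC
integrates the full threshold sweep by the trapezoidal rule with threshold
ties collapsed (cross-checked against pROC in the tests); PR-AUC uses step
interpolation; the calibration curve uses 10 equal-width bins on [0, 1].
The paired-fold t-test is the classical two-sided paired t with
`df = k - 1` and a t-quantile confidence interval; zero-variance
differences return an exact-tie report instead of a statistic.

The comparison report evaluates the full 3-stage x 4-learner grid (12
rows), formats the four headline metrics as percentages to two decimals,
flags the best accuracy row, and isolates per-model failures so one broken
configuration cannot void the report.

## Local explanations

Explanations fit a proximity-weighted sparse linear surrogate to the
model's probabilities around one instance. Binary features are resampled
uniformly from {0, 1} (flip rate 1/2 relative to the instance) for
symmetric coverage — prevalence-based sampling is available by flag —
and continuous features get Gaussian jitter at the cohort SD; zero-SD
features are left unperturbed. The proximity kernel is
`exp(-d^2 / width^2)` with default width `0.75 * sqrt(p)`; the distance
counts one unit per binary flip and SD-standardizes continuous
coordinates. Dividing binary flips by the cohort SD instead would let rare
indicators (prevalence ~0.006, SD ~0.08) contribute enormous distances,
collapsing the effective perturbation sample — this scale choice is the
package's own.

The surrogate screens the `max_features = 10` columns with the largest
absolute weighted covariance on the SD-standardized scale (covariance
screening rather than forward selection, for determinism), then solves a
ridge-stabilized weighted least squares (`lambda = 1e-10` times the mean
Gram diagonal — stabilization only, so exact linear models are recovered
to solver tolerance with weighted R-squared 1). Features outside the
fitted model's mask are excluded from screening and reported with weight
exactly 0. A constant model short-circuits to zero weights with fidelity
defined as 1. Explanations report the model's probabilities, not labels;
ranking is by absolute weight with ties broken by feature order, and a
fixed seed makes the whole explanation byte-identical.

## Reproducibility and problem sizes

A single global seed fans out to per-component seeds through a recorded
deterministic derivation (`derive_seed()`), so folds, SMOTE draws, learner
fits, the ABC trajectory and explanations are each independently
reproducible and the manifest accounts for every random draw. The test
suite exercises the pipeline at cohort sizes 80-300 with the full grid at
n = 200, generator-fidelity checks at n = 100,000, optimizer
oracle-equivalence on binary spaces of dimension 6 and 8 against exhaustive
enumeration, and 2,000-replicate calibration of the paired t-test — sizes
chosen so each property is measured with comfortable Monte-Carlo margin at
desk scale.

## Limitations

The generator's independence assumption and marginal-only fidelity mean
synthetic results bound algorithmic, not clinical, performance. Binary
supplement encoding discards dose, duration and adherence by design. The
three-stage comparison applies no multiple-testing correction across the
12-model grid. The ABC search optimizes an inner-CV estimate and, like any
wrapper selector on small cohorts, can overfit the selection criterion;
the outer CV guards the reported scores but not the chosen mask itself.
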