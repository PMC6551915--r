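---
title: "Integrated structure + mechanism-of-action activity modeling with qsmartr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated structure + mechanism-of-action activity modeling with qsmartr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

Classical QSAR regresses a biological endpoint on molecular descriptors
(MDs) alone. qsmartr implements the QSMARt extension: the design matrix
fuses an MD block with one gene log fold-change block per treated cell
line, so the model can attribute part of the activity to the compound's
mechanism of action (MOA). The working endpoint throughout the package's
examples is logK_HSA, the log binding constant to human serum albumin
measured by immobilized-HSA affinity chromatography, but nothing in the
code is specific to that endpoint.

The model is linear in a block-wise power transformation of the absolute
feature values,

    y = X(alpha, gamma) beta + epsilon,

where X(alpha, gamma) applies `|x|^alpha` to every MD column and
`|x|^gamma` to every gene column (the same gamma for all cell lines, both
exponents strictly positive), and beta is estimated by the lasso,

    argmin ||y - X(alpha, gamma) beta||^2 + penalty * ||beta||_1,

with an unpenalized intercept. The exponent pair is treated as a discrete
hyper-parameter: a 9 x 9 grid over {0.1, 0.25, 0.5, 0.75, 1, 1.25, 1.5,
1.75, 2} gives 81 candidate models, each validated independently, and the
final model is chosen by eligibility criteria plus parsimony and
applicability-domain tie-breaks.

## Penalty scaling convention

Internally the solver minimizes

    (1/(2n)) ||y - b0 - X beta||^2 + lambda ||beta||_1

on columns standardized to mean zero and unit population variance, with
coefficients reported back on the transformed (unstandardized) scale.
This per-observation scaling is the same minimizer as the unscaled
objective with penalty `2 n lambda`; it is used so that (a) the penalty
path `lambda_max = max_j |x_j'(y - mean(y))|/n` makes the first path
point exactly the all-zero fit (the KKT entry condition), and (b) lambda
values are comparable across sample sizes. Published penalty values
obtained under other conventions are not directly comparable to this
package's lambda without rescaling.

The path holds 100 values, log-spaced over three decades down from
`lambda_max`. Both the count and the ratio are tunable
(`n_lambdas`, and the ratio is fixed at 1e-3 in `lambda_path()`).

## Solver numerics

The estimator is solved by cyclic coordinate descent (compiled code),
with warm starts along the decreasing penalty path and an active-set
strategy. For moderate column counts the solver precomputes X'X and
maintains the full gradient (covariance updating), so late sweeps cost
O(p) per changed coefficient; above 800 columns it falls back to residual
updating.

Convergence is declared when the largest absolute coefficient change in a
full sweep falls below `tol = 1e-7` (standardized scale), with a budget
of 1e5 sweeps in `fit_lasso()`. Strong power compression (exponents near
0.1) makes many transformed columns almost collinear, and coordinate
descent can then drift along a flat ridge: the objective is at its
minimum while coefficients keep sliding. Two guards handle this without
weakening the user-facing contract:

* if the objective decreases by less than 1e-12 (relative) over a sweep,
  the solve stops early; it counts as converged only when the coefficient
  movement is already prediction-stable (below `sqrt(tol)`), otherwise it
  is flagged non-converged;
* `select_lambda()` — the screening stage that only needs validation MSE —
  runs each penalty under a reduced sweep budget (default 300,
  `select_sweeps` in `grid_search()`) and stops a split's path early once
  a fit saturates (more nonzero coefficients than training rows, i.e. an
  interpolating fit). Penalties that do not converge on every split get
  infinite MSE and cannot be selected; `fit_lasso()` itself still errors
  on non-convergence.

The rationale: penalties whose fits cannot be computed stably at the
screening tolerance sit deep in the overfitting tail, where validation
MSE is already rising; excluding them changes no defensible selection and
removes a pathological compute sink.

## RSVA: repeated stratified splitting

All splits are stratified on the response, cut into three equal-frequency
bins (tertiles; quantile type 7 edges). Equal-frequency bins were chosen
over equal-width because a skewed response otherwise starves a bin. Within
each bin the seeded shuffle sends `ceiling(bin_size * train_frac)`
compounds to the training side, capped at `bin_size - 1` so every bin of
two or more compounds appears on both sides; the remainder is the
holdout. The outer partition uses `train_frac = 0.8` (59 compounds give
the canonical 48/11), the inner RSVA ensemble uses 100 splits at 0.9 with
seeds `base_seed + i - 1`.

Per-split metrics are aggregated as the 60th percentile across splits,
using linear interpolation between order statistics (quantile type 7), so
the aggregate is bit-reproducible.

## Validation statistics

`r_squared()` is the ordinary determination coefficient. The external
coefficients follow the standard definitions: Q2F1 references the
training mean, Q2F2 the test mean, and Q2F3 normalizes the test PRESS and
the training variance by their sample sizes (making it invariant to
duplicating test compounds). `ccc()` is Lin's concordance correlation.
`q2_l10o()` runs repeated stratified 10-fold cross-validation (10
repetitions by default, seeded) and averages the per-repetition
`1 - PRESS/SS_tot`; a single pass would be cheaper but noticeably
noisier at 48 training compounds.

## Applicability domain

Five methods are computed in the space the model actually sees: the
selected features after power transformation.

* Leverage: `h = x'(X'X)^{-1}x` against the training design with
  intercept; warning leverage `h* = 3(k+1)/n`. Response outliers are
  |standardized residual| > 3, where the scale is the training residual
  RMSE. Williams-plot data (h vs standardized residual) are returned.
* Standardization: any feature beyond 3 training SDs marks the compound
  outside (three-sigma rule).
* Euclidean and city-block distance to the training centroid, threshold
  at the farthest training compound.
* kNN: mean Euclidean distance to the k = 3 nearest training neighbours
  (self excluded for the training scores); threshold at the largest
  training score. The mean of the k distances is used — "distance to the
  k nearest neighbours" is also read as the maximum by some authors; the
  mean is the recorded choice here.

All out-of-domain comparisons are strict (`>`), so a compound exactly on
a threshold is inside. The consensus averages binary in-domain votes —
leverage and standardization for training compounds, all five methods for
test compounds — and calls a compound in-domain at score >= 0.5 (so a 1/2
training vote is inside). Averaging votes rather than coverage
percentages keeps a per-compound verdict. The Insubria graph classifies
response-free compounds by leverage (interpolated vs extrapolated at h*)
and by the model's prediction range.

## Grid search and final-model choice

Each grid cell: penalty path on the outer training block, penalty chosen
by mean validation MSE across the RSVA splits (ties to the larger
penalty), refit on the whole training set, external validation on the
held-back 20%, full AD report. Cells whose selected fit is empty are kept
as ineligible placeholders — the gene-only view genuinely produces such
cells under weak signal, and they must be visible in the candidates
table.

Eligibility requires R2_train, R2_test, Q2_L10O, Q2F1, Q2F2, Q2F3 >= 0.6
and consensus AD_Test = 100%. The concordance threshold (0.85) is
reported but non-blocking by default, since a model can clear every
determination coefficient while falling short on concordance; strict mode
(`ccc_blocking = TRUE`) makes it blocking. Among eligible candidates the
prediction error E is the test-set MSE — the procedure names only "best
predictive performance", and test MSE is the matching concrete choice —
with ties broken by fewer features, then wider AD_Train, then smaller
grid index. The full ranking is returned for audit.

The correlation filter (|r| > 0.95, later column dropped — a
deterministic, order-stable rule) and the constant filter (modal share
strictly above 80%) are applied to the descriptor block before any
split. Whether the original workflow also filtered the gene blocks is not
documented; the package filters per block but `run_config()` defaults to
descriptor-only filtering (`filter_genes = FALSE`).

## Synthetic data

`generate()` emulates the fused-input geometry at toy scale. MD columns
cycle through signed uniforms of mixed scale, heavy-tailed log-normals,
and Poisson counts (some sparse) — a caricature of descriptor
heterogeneity; gene columns are Normal(0, 0.5), a caricature of logFC
dispersion. A few bait columns exercise the filters: near-constant
columns (modal share 0.9) and exact duplicate pairs, never part of the
planted support. The response is
`intercept + X(alpha0, gamma0) beta0 + Normal(0, noise_sd)` with each
active coefficient scaled so its contribution has SD `beta_scale` times
Uniform(0.5, 1.5) — without this, heavy-tailed columns would dominate and
gene features would be undetectable at any fixed coefficient size.

Defaults: 100 compounds, 50 MDs, 50 genes in each of two cell lines,
support of 3 MDs + 1 gene per line (5 features), `(alpha0, gamma0) =
(1.25, 1.75)` — the exponent pair of the published integrated model —
`beta_scale = 1`, `noise_sd = 0.1`. One RNG stream per call, seeded from
the spec.

What the generator does **not** emulate: realistic descriptor
correlation structure (beyond the planted duplicates), probe-level
microarray noise, batch effects, or any real structure–expression
coupling. Tests passing on this generator demonstrate the machinery —
filtering, selection consistency, calibration under the null — not
field performance on real chemistry.

## Problem sizes used by the test suite

The recovery studies run 50 seeded replicates at n = 100, p = 150,
noise 0.1: support recovery uses the true transform with 10 RSVA splits;
the grid-winner study runs the full 81-cell search with 5 splits and a
100-sweep screening budget per penalty; the null calibration runs 20
replicates at n = 60. These sizes are the package's own choice of a
desk-scale experiment that is statistically meaningful for the properties
asserted (≥ 90% support recovery, ≥ 80% winner identity, ≥ 95% clean
null runs).

## Known limitations

* Penalty values are convention-bound (see above) and not comparable
  across software without rescaling.
* The two bundled single-view models carry exponents (0.11, 0.16) that do
  not lie on the default grid; their provenance is an independent
  optimization that the package can express (arbitrary grids) but not
  reconstruct.
* The bundled final model ships without its training data, so its
  prediction range and training design must be supplied by the user for
  Insubria screening (`screen_external()` accepts a surrogate design and
  labels it as such in the docs).
* Empty-model cells are reported with NA metrics rather than refused;
  downstream selection treats them as ineligible.
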