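---
title: "Growth curves, inflection points and MARS for broiler weight data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth curves, inflection points and MARS for broiler weight data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockfit)
```

## The problem

A broiler flock is weighed weekly from hatch to slaughter. Two questions
recur: which parametric growth law describes the trajectory best, and at what
age is the weekly gain maximal (the inflection point, which drives feeding
and marketing decisions)? `flockfit` answers both, and adds a nonparametric
alternative — a single-predictor MARS model — for trajectories that no single
sigmoid fits well.

## The parametric models and their assumptions

All five families share the same structure: a monotone curve rising from a
small hatch weight towards a mature asymptote `A` (grams), with a weekly rate
constant and one or two shape parameters. Units are fixed package-wide (age
in weeks, weight in grams); conversions are the caller's job.

Several published typesettings of these equations are ambiguous; the forms
implemented here are the ones whose predictions are internally consistent
with the curves' standard behaviour (weight rising from a positive hatch
value towards `A`) and with their own inflection formulas:

* logistic `A/(1 + b e^{-kt})` — hatch weight `A/(1+b)`, inflection at
  `A/2`. Symmetric around the inflection.
* Gompertz `A exp(-b e^{-kt})` — asymmetric, inflection at `A/e` (about 37%
  of mature weight), usually the best fit for broilers.
* Weibull `A − b e^{-k t^λ}` — hatch weight `A − b`; the inflection exists
  only for `λ > 1`, at weight `A − b e^{-(1−1/λ)}`. `A` and `b` are strongly
  correlated on short series, and `k` trades off against `λ`.
* Hossfeld `A(1 + b1 t^{-b2})^{-1}` — requires `b1 > 1`; the inflection
  (`b2 > 1`) lies at `[b1(b2−1)/(b2+1)]^{1/b2}` weeks and `A(b2−1)/(2b2)` g.
  The term `t^{-b2}` diverges at `t = 0`; the curve is extended there by its
  continuity limit, `Y(0) = 0`. A consequence is that exactly-at-hatch
  records cannot be generated from (or validated against) a Hossfeld curve,
  since weights must be positive.
* von Bertalanffy `A(1 − b e^{-kt})^3` — inflection at `8A/27` when
  `3b ≥ 1`. The rate constant multiplies a *decaying* exponential; a rising
  exponential would not grow towards `A`.

When parameters place the inflection at a negative age (e.g. logistic with
`b < 1`), `inflection()` signals a `flockfit_no_inflection` condition rather
than returning an extrapolated point.

## Fitting

`fit_growth()` minimises the ordinary (unweighted) sum of squared residuals.
Weighted (relative-error) fitting is available via
`fit_control(weighted = TRUE)` but is off by default: unweighted least
squares on the weights is the standard reporting convention for these models,
and the comparison criteria are defined on the same scale.

Numerical choices:

* **Initialisation** is deterministic: `A₀ = 1.2 × max(weight)`, then each
  family is log-linearised with `A` fixed at `A₀` (e.g.
  `ln(A₀/w − 1) = ln b − k t` for the logistic) and the slope/intercept give
  `k₀` and `b₀`. For Weibull the shape starts at `λ₀ = 2`; for Hossfeld the
  regression of `ln(A₀/w − 1)` on `ln t` gives `b1₀`, `b2₀` (fallback 10 and
  2 when fewer than two positive-age records exist).
* **Multi-start**: 8 seeded log-uniform perturbations (each parameter scaled
  by up to ×3 or ÷3) of the deterministic start. Weibull and Hossfeld have
  flat, correlated objectives on 7-point series; the restarts make recovery
  robust without sacrificing determinism (the seed lives in
  `fit_control()`).
* **Bounds** keep every iterate in the model domain and every inflection
  formula defined: `A ∈ (max weight, 50 × max weight)`, `k ∈ (10⁻⁶, 10)`,
  `λ, b2 ∈ (1 + 10⁻³, 10)`, `b1 ∈ (1 + 10⁻³, 10⁴)`.
* **Convergence** is Levenberg–Marquardt (via `minpack.lm`) with relative
  SSE tolerance `10⁻¹⁰`, gradient tolerance `10⁻⁸`, at most 500 iterations
  per start; the best converged start by SSE wins, and the objective never
  exceeds the objective at the deterministic start. Degenerate inputs
  (constant weights, fewer distinct ages than parameters plus one) raise a
  `flockfit_insufficient_data` condition instead of returning a fit.

Parameter sets estimated on per-bird records (like the packaged reference
parameters) are *evaluation inputs*, not fitting targets: refitting on the
seven flock means gives a different, lower-SSE solution because the means
carry far less information than the individual birds.

## The MARS engine

`fit_mars()` implements single-predictor, additive, degree-1 MARS:

* **Candidate knots** default to the distinct observed ages. With weekly
  weighings the observed ages are the only meaningful breakpoints, and they
  make fits deterministic; a seeded uniform random grid
  (`knots = "random"`) is available for fidelity to the classical algorithm.
* **Forward pass**: at each step every candidate knot is tried; the
  reflected hinge pair at that knot is added, unless one side is collinear
  with the current basis (e.g. the descending hinge at the smallest age) or
  there is no room, in which case a single hinge is added. Coefficients are
  refit by exact linear least squares at every step. RSS ties break to the
  smaller knot, then pair before single-above before single-below.
* **Backward pass**: terms are deleted one at a time (the deletion that
  least increases RSS), and the model with the smallest GCV along the
  deletion sequence is returned. The effective model size in
  `GCV = (RSS/n)/(1 − M/n)²` is `M = (#coefficients) + d × (#knots)` with
  `d = 2`, the usual additive-model convention; `d` is configurable because
  published analyses rarely state it. Models whose effective size reaches
  `n` have undefined GCV; inside pruning they are treated as infinitely bad,
  while the exported `gcv()` raises an error.
* With 7 weekly means the GCV penalty at `d = 2` is severe: any model with
  two or more distinct knots has `M ≥ 7 = n`, so pruned models keep at most
  one knot. For interpolation-style fits on few points, `prune = FALSE`
  returns the full forward model (which reaches R² ≈ 1 on the packaged
  means).

## The simulator

`simulate_flock()` generates the data structure the analysis assumes: bird
`i` receives its own asymptote `Aᵢ = A(1 + c_A zᵢ)` (the simplest
exchangeable form of between-bird heterogeneity — the data offer no
covariance information to justify more), and every weighing is perturbed
multiplicatively, `w = Y(t; Aᵢ)(1 + c_e ε)`, truncated below at 1 g.
Multiplicative noise is the realistic default because weights span roughly
48 g to 2200 g over six weeks, so a constant-CV error model matches how scale
error actually behaves; a constant-SD additive option exists for textbook
homoscedastic experiments. The truncation is a deliberate deviation from pure
Gaussian noise that only matters at extreme noise levels.

Defaults mirror a commercial fattening trial: 192 birds, weekly weighings at
ages 0–6, 8% asymptote CV, 5% measurement CV. What the simulator does *not*
emulate: serial correlation within a bird beyond the shared asymptote,
feed/sex/treatment effects, mortality and culling, or growth beyond week 6 —
so recovery results on simulated flocks demonstrate estimator correctness
under the stated model, not robustness to real-world artefacts.

The package's recovery checks run at reduced scale (10–20 seeds, 50-bird
flocks) to keep the default test suite fast; the estimator itself has no
scale limitation.

## Known limitations and flagged inconsistencies

* Published Weibull inflection *weights* computed with rounded parameter
  tables can disagree wildly with the `A − b e^{-(1−1/λ)}` formula because
  `A − b` is a small difference of two large correlated estimates. The
  package always reports the formula value.
* The packaged reference MARS model is not a fully paired hinge set (its
  knot-1 and knot-4 terms have no mirrored partners); `mars_model()` accepts
  any term list, so such externally specified models evaluate exactly as
  written.
* No standard errors or confidence intervals for curve parameters are
  produced, and no per-bird random-coefficient (mixed-effects) fitting is
  attempted; all records are pooled in the least-squares loss.

## A worked comparison

```{r compare}
d <- broiler_weekly_weights()
cmp <- compare_growth(d)
cmp$criteria[, c("family", "r2", "mse", "aic", "bic", "ipt", "ipw")]
cmp$best
```

```{r plot, fig.width = 7, fig.height = 4.5}
autoplot(cmp)
```
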