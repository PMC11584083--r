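# flockfit

Growth-curve and spline models for broiler body-weight data.

Commercial broilers are weighed weekly from hatch to slaughter (about six
weeks), and producers choose feeding and marketing schedules from the fitted
growth trajectory. `flockfit` fits and compares the five classical sigmoidal
growth models used for poultry live weight, reports each model's inflection
point (the age and weight of maximal weekly gain), and fits a single-predictor
multivariate adaptive regression spline (MARS) as a flexible, knot-based
alternative. All user-facing functions take a data frame of age–weight records
and return tibbles, so the package composes with the tidyverse.

## Models

With age `t` in weeks and weight `Y` in grams, the parametric families are

| family | curve | inflection age `IPT` | inflection weight `IPW` |
|---|---|---|---|
| logistic | `A / (1 + b e^{-kt})` | `ln(b)/k` | `A/2` |
| Gompertz | `A exp(-b e^{-kt})` | `ln(b)/k` | `A/e` |
| Weibull | `A - b exp(-k t^λ)` | `[(λ-1)/(kλ)]^{1/λ}` | `A - b e^{-(1-1/λ)}` |
| Hossfeld | `A (1 + b1 t^{-b2})^{-1}` | `[b1(b2-1)/(b2+1)]^{1/b2}` | `A(b2-1)/(2 b2)` |
| von Bertalanffy | `A (1 - b e^{-kt})^3` | `ln(3b)/k` | `8A/27` |

`A` is the mature (asymptotic) weight, `k` a weekly rate constant, `b` an
initial-size parameter, and `λ`, `b1`, `b2` shape parameters. Fitting is
bounded Levenberg–Marquardt nonlinear least squares with deterministic
initial values and a seeded multi-start fallback.

The MARS model is `f(x) = β0 + Σ βm·hm(x)` with hinge basis functions
`max(0, x−t)` / `max(0, t−x)`, grown by greedy forward knot selection and
pruned backwards by generalized cross-validation,
`GCV = (RSS/n) / (1 − M/n)²`, where `M` counts coefficients plus a per-knot
penalty. The MARS engine is implemented in the package itself.

Model comparison uses `MSE = SSE/n`, `RMSE`, `R²`, adjusted `R²`,
`AIC = n ln(SSE/n) + 2k` and `BIC = n ln(SSE/n) + k ln n`.

## Worked example

The packaged dataset `broiler_weekly_weights()` holds the weekly mean live
weights of a male broiler flock (Ross PM3) from hatch to week 6.

```r
library(flockfit)

d <- broiler_weekly_weights()
fit <- fit_growth(d, "gompertz")
fit
#> <growth_fit> gompertz on 7 records
#>         A         b         k
#> 8295.2575    5.0162    0.2217
#> SSE 1661.1885  R2 0.99957  AIC 44.286  BIC 44.123
#> inflection at 7.275 weeks, 3051.655 g
```

The fitted mature weight is about 8295 g with weekly rate constant 0.22; the
week of maximal gain (7.3) falls just beyond the observation window, which is
typical when only the accelerating part of the trajectory is observed.
Comparing all five families:

```r
fits <- fit_growth_all(d)
rank_models(fits, "aic")[, c("rank", "family", "r2", "mse", "aic")]
#>    rank family             r2   mse   aic
#>       1 gompertz        1.000  237.  44.3
#>       2 logistic        0.999  344.  46.9
#>       3 von_bertalanffy 0.999  370.  47.4
#>       4 hossfeld        0.997 1473.  57.1
#>       5 weibull         0.997 1446.  58.9
```

The Gompertz curve gives the lowest MSE/AIC/BIC and the highest R² on this
flock. A MARS fit on the same data (`fit_mars(d)`) places its knots at the
ages where the weekly slope changes; `tidy()`, `glance()` and `autoplot()`
methods summarise any fitted object, and `compare_growth()` +
`write_growth_report()` produce the parameter/criteria/prediction tables as
CSV and JSON. `inst/cli/flockfit.R` wraps the same pipeline for shell use.

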