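ref <- broiler_reference_parameters()

test_that("closed-form curves reproduce known single-point values", {
  # logistic at hatch: A / (1 + b)
  expect_equal(round(growth_curve(ref$logistic, 0), 2), 82.32)
  # weibull at hatch: A - b, independent of k and lambda
  expect_equal(round(growth_curve(ref$weibull, 0), 2), 64.20)
  expect_equal(growth_curve(ref$weibull, 0),
               ref$weibull$params[["A"]] - ref$weibull$params[["b"]])
  # hossfeld at 6 weeks, frozen from direct evaluation of the resolved form
  expect_equal(growth_curve(ref$hossfeld, 6), 2137.233, tolerance = 1e-6)
  # hossfeld at age 0: continuity limit
  expect_identical(growth_curve(ref$hossfeld, 0), 0)
})

test_that("every family approaches its asymptote at large age", {
  for (fam in all_families()) {
    p <- ref[[fam]]
    expect_equal(growth_curve(p, 1e6), p$params[["A"]],
                 tolerance = 1e-6, info = fam)
  }
})

test_that("invalid parameters and negative ages are rejected", {
  expect_error(growth_params("logistic", A = -5, b = 2, k = 0.5), "A must be > 0")
  expect_error(growth_params("gompertz", A = 100, b = 2, k = -1), "k must be > 0")
  expect_error(growth_params("hossfeld", A = 100, b1 = 0.5, b2 = 2), "b1 must be > 1")
  expect_error(growth_params("weibull", A = 100, b = 90, k = 0.1), "missing")
  expect_error(growth_params("logistic", A = 100, b = 2, k = 0.5, lambda = 2),
               "not defined")
  expect_error(growth_curve(ref$hossfeld, -1), "non-negative")
  expect_error(growth_curve(ref$logistic, c(1, -2)), "non-negative")
})

test_that("inflection points match the closed forms on the reference curves", {
  gi <- inflection(ref$gompertz)
  expect_equal(gi$ipt, 6.579, tolerance = 2e-3 / 6.579)
  expect_equal(gi$ipw, 2521.578, tolerance = 0.01 / 2521.578)
  expect_equal(inflection(ref$logistic)$ipw, ref$logistic$params[["A"]] / 2)
  expect_equal(round(inflection(ref$von_bertalanffy)$ipt, 3), 11.354)
  expect_equal(round(inflection(ref$weibull)$ipt, 3), 10.556)
  hi <- inflection(ref$hossfeld)
  expect_equal(hi$ipt, 6.074, tolerance = 2e-3 / 6.074)
  expect_equal(hi$ipw, 2176.271, tolerance = 0.01 / 2176.271)
})

test_that("inflection handles boundary and undefined cases", {
  expect_equal(inflection(growth_params("gompertz", A = 100, b = 1, k = 0.3))$ipt, 0)
  expect_error(inflection(growth_params("weibull", A = 100, b = 90, k = 0.1,
                                        lambda = 0.9)),
               class = "flockfit_no_inflection")
  expect_error(inflection(growth_params("hossfeld", A = 100, b1 = 10, b2 = 0.8)),
               class = "flockfit_no_inflection")
  # logistic with b < 1 has its inflection before hatch
  expect_error(inflection(growth_params("logistic", A = 100, b = 0.5, k = 0.3)),
               class = "flockfit_no_inflection")
})

test_that("curves are strictly increasing and bounded above by A", {
  grid <- seq(0.01, 60, length.out = 400)
  for (fam in all_families()) {
    for (seed in 1:3) {
      p <- random_params(fam, seed)
      A <- p$params[["A"]]
      w <- growth_curve(p, grid)
      expect_true(all(diff(w) >= 0), info = paste(fam, seed))
      # strictly increasing wherever the curve is numerically below A
      unsaturated <- w[-1] < A * (1 - 1e-12)
      expect_true(all(diff(w)[unsaturated] > 0), info = paste(fam, seed))
      expect_true(all(w <= A + 1e-9), info = paste(fam, seed))
    }
  }
})

test_that("inflection weight formulas agree with the curve at the inflection age", {
  for (fam in all_families()) {
    for (seed in 4:8) {
      p <- random_params(fam, seed)
      ip <- tryCatch(inflection(p), flockfit_no_inflection = function(e) NULL)
      if (is.null(ip)) next
      expect_equal(growth_curve(p, ip$ipt), ip$ipw, tolerance = 1e-8,
                   info = paste(fam, seed))
      if (fam == "logistic") expect_equal(ip$ipw, p$params[["A"]] / 2)
      if (fam == "gompertz") expect_equal(ip$ipw, p$params[["A"]] / exp(1))
    }
  }
})

test_that("the second derivative changes sign across the inflection age", {
  for (fam in all_families()) {
    p <- random_params(fam, 11)
    ip <- tryCatch(inflection(p), flockfit_no_inflection = function(e) NULL)
    if (is.null(ip) || ip$ipt < 0.1) next
    expect_gt(num_d2(p, ip$ipt - 0.05), 0, label = paste(fam, "d2 before"))
    expect_lt(num_d2(p, ip$ipt + 0.05), 0, label = paste(fam, "d2 after"))
  }
})

test_that("vectorised evaluation preserves length and matches scalar calls", {
  p <- ref$gompertz
  expect_identical(growth_curve(p, numeric(0)), numeric(0))
  expect_equal(growth_curve(p, 3), growth_curve(p, c(3)))
  w <- growth_curve(p, 0:6)
  expect_length(w, 7)
  expect_true(all(diff(w) > 0))
  expect_equal(w[4], growth_curve(p, 3))
})
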