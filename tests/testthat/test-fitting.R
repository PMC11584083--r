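ref <- broiler_reference_parameters()
weekly <- broiler_weekly_weights()

test_that("initial values start the asymptote at 1.2 x the observed maximum", {
  s <- initial_growth_values(weekly, "gompertz")
  expect_equal(s$params[["A"]], 1.2 * 2193.10)
})

test_that("initialization followed by fitting recovers noise-free logistic data", {
  p <- random_params("logistic", 21)
  d <- tibble::tibble(age_weeks = 0:9,
                      weight_g = growth_curve(p, 0:9))
  f <- fit_growth(d, "logistic")
  expect_true(f$converged)
  expect_equal(unname(f$params$params), unname(p$params), tolerance = 1e-4)
})

test_that("degenerate data is refused, never silently fitted", {
  const <- tibble::tibble(age_weeks = 0:6, weight_g = rep(500, 7))
  expect_error(fit_growth(const, "gompertz"),
               class = "flockfit_insufficient_data")
  expect_error(initial_growth_values(const, "gompertz"),
               class = "flockfit_insufficient_data")
  few <- tibble::tibble(age_weeks = c(0, 1, 2), weight_g = c(50, 150, 350))
  expect_error(fit_growth(few, "logistic"),
               class = "flockfit_insufficient_data")
})

test_that("fitting the weekly means beats the reference parameters' SSE", {
  bound <- sum((weekly$weight_g - growth_curve(ref$gompertz, weekly$age_weeks))^2)
  f <- fit_growth(weekly, "gompertz")
  expect_lte(f$sse, bound)
  expect_gte(f$gof$r2, 0.999)
})

test_that("noise-free curves from reference parameters are recovered", {
  tol <- c(logistic = 1e-3, gompertz = 1e-3, weibull = 1e-2,
           hossfeld = 1e-3, von_bertalanffy = 1e-3)
  for (fam in all_families()) {
    p <- ref[[fam]]
    ages <- if (fam == "hossfeld") 1:7 else 0:6  # hossfeld weight is 0 at hatch
    d <- tibble::tibble(age_weeks = ages, weight_g = growth_curve(p, ages))
    f <- fit_growth(d, fam)
    rel <- abs(f$params$params - p$params) / abs(p$params)
    expect_lt(max(rel), tol[[fam]], label = paste(fam, "max relative error"))
  }
})

test_that("refitting from the solution is a fixed point of the optimizer", {
  f1 <- fit_growth(weekly, "gompertz")
  f2 <- fit_growth(weekly, "gompertz", control = fit_control(n_starts = 0),
                   start = f1$params)
  expect_equal(f2$sse, f1$sse, tolerance = 1e-10)
})

test_that("fitted SSE is invariant to record order and runs are deterministic", {
  f1 <- fit_growth(weekly, "weibull")
  f2 <- fit_growth(weekly, "weibull")
  expect_identical(f1$params$params, f2$params$params)
  shuffled <- weekly[c(4, 1, 7, 3, 6, 2, 5), ]
  f3 <- fit_growth(shuffled, "weibull")
  expect_equal(f3$sse, f1$sse, tolerance = 1e-8)
})

test_that("median parameter bias is small on noisy simulated flocks", {
  # 50 birds x 7 weeks, 2% multiplicative measurement error, 10 seeds
  for (fam in c("gompertz", "logistic")) {
    p <- ref[[fam]]
    bias_A <- bias_k <- numeric(10)
    for (s in 1:10) {
      sim <- simulate_flock(p, n_birds = 50, ages = 0:6, asymptote_cv = 0,
                            noise_cv = 0.02, seed = s)
      f <- fit_growth(sim, fam, fit_control(seed = s))
      bias_A[s] <- (f$params$params[["A"]] - p$params[["A"]]) / p$params[["A"]]
      bias_k[s] <- (f$params$params[["k"]] - p$params[["k"]]) / p$params[["k"]]
    }
    expect_lt(median(abs(bias_A)), 0.02, label = paste(fam, "A bias"))
    expect_lt(median(abs(bias_k)), 0.02, label = paste(fam, "k bias"))
  }
})

test_that("fit_growth_all fits every family on the weekly means", {
  fits <- fit_growth_all(weekly)
  expect_s3_class(fits, "growth_fit_list")
  expect_named(fits, all_families())
  g <- glance(fits)
  expect_true(all(g$converged))
  expect_true(all(g$r2 > 0.99))
})

test_that("fit_growth_all records per-family failures without aborting", {
  four <- tibble::tibble(age_weeks = 0:3,
                         weight_g = growth_curve(ref$gompertz, 0:3))
  fits <- fit_growth_all(four)
  expect_s3_class(fits$weibull, "growth_fit_failure")  # 4-parameter family
  expect_true(any(vapply(fits, inherits, logical(1), "growth_fit")))
  two <- tibble::tibble(age_weeks = c(0, 1), weight_g = c(50, 150))
  expect_error(fit_growth_all(two), "all families failed")
})

test_that("tidiers expose parameters and fit summaries", {
  f <- fit_growth(weekly, "gompertz")
  td <- tidy(f)
  expect_equal(td$term, c("A", "b", "k"))
  gl <- glance(f)
  expect_equal(gl$family, "gompertz")
  expect_true(all(c("aic", "bic", "ipt", "ipw") %in% names(gl)))
  au <- augment(f)
  expect_equal(au$.resid, au$observed - au$fitted)
})
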