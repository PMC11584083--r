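weekly <- broiler_weekly_weights()

published_hinge_model <- function() {
  read_model_json(system.file("extdata", "broiler_mars_model.json",
                              package = "flockfit"))
}

# independent oracle: exhaustive OLS over every single-knot basis
# (pair, above only, below only) at the observed predictor values
single_knot_best_rss <- function(x, y) {
  best <- Inf
  for (t in sort(unique(x))) {
    bases <- list(cbind(1, pmax(0, x - t), pmax(0, t - x)),
                  cbind(1, pmax(0, x - t)),
                  cbind(1, pmax(0, t - x)))
    for (B in bases) {
      qrB <- qr(B)
      if (qrB$rank < ncol(B)) next
      best <- min(best, sum(qr.resid(qrB, y)^2))
    }
  }
  best
}

random_dataset <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(7:12, 1)
    x <- sort(round(stats::runif(n, 0, 8), 2))
    y <- 100 + 40 * x + 30 * pmax(0, x - sample(3:5, 1)) +
      stats::rnorm(n, sd = 15)
    tibble::tibble(age_weeks = x, weight_g = pmax(y, 1))
  })
}

test_that("hinge functions follow the two-sided truncation rules", {
  expect_equal(hinge(5, 1, "above"), 4)
  expect_equal(hinge(5, 3, "below"), 0)
  expect_equal(hinge(3, 3, "above"), 0)
  expect_equal(hinge(3, 3, "below"), 0)
  expect_equal(hinge(c(0, 2, 4), 3, "below"), c(3, 1, 0))
  expect_true(all(hinge(seq(-5, 5, 0.5), 1.3, "above") >= 0))
})

test_that("an externally specified hinge model reproduces its printed predictions", {
  m <- published_hinge_model()
  expect_equal(round(predict(m, 0), 2), 46.74)
  expect_equal(round(predict(m, 5), 2), 1586.73)
  expect_equal(round(predict(m, 3), 2), 588.05)
  # empty-term model predicts its intercept everywhere
  m0 <- mars_model(intercept = 42)
  expect_equal(predict(m0, c(0, 3, 100)), rep(42, 3))
})

test_that("the GCV score matches its closed form and rejects oversized models", {
  expect_equal(gcv(0, 7, 3), 0)
  expect_equal(gcv(700, 7, 0), 100)
  expect_equal(gcv(700, 7, 3.5), 400)
  expect_error(gcv(700, 7, 7), class = "flockfit_gcv_undefined")
  expect_error(gcv(700, 7, 9), class = "flockfit_gcv_undefined")
  expect_error(gcv(-1, 7, 2), "non-negative")
})

test_that("data on a straight line is fit exactly", {
  d <- tibble::tibble(age_weeks = 0:6, weight_g = 2 * (0:6) + 1)
  f <- fit_mars(d)
  expect_lt(f$rss, 1e-8)
  expect_lt(f$model$gcv, 1e-8)
})

test_that("a single slope change is located at the true knot", {
  x <- 0:6
  y <- 10 + 2 * x + 5 * pmax(0, x - 3)  # kink at age 3, no noise
  f <- fit_mars(tibble::tibble(age_weeks = x, weight_g = y))
  expect_true(3 %in% f$model$terms$knot)
  expect_lt(f$rss, 1e-8)
})

test_that("the unpruned forward model interpolates the weekly means", {
  f <- fit_mars(weekly, prune = FALSE)
  expect_gte(f$r2, 0.999)
})

test_that("the forward pass' first step matches an exhaustive single-knot search", {
  for (seed in 1:10) {
    d <- random_dataset(seed)
    f <- fit_mars(d)
    oracle <- single_knot_best_rss(d$age_weeks, d$weight_g)
    first <- f$forward$rss[f$forward$step == 1]
    expect_equal(first, oracle, tolerance = 1e-8, info = paste("seed", seed))
  }
})

test_that("backward pruning selects the GCV minimum of the deletion sequence", {
  for (seed in 1:5) {
    f <- fit_mars(random_dataset(seed))
    expect_equal(f$model$gcv, min(f$prune_path$gcv), info = paste("seed", seed))
    expect_lte(f$model$gcv, f$prune_path$gcv[1])  # never above the forward model
  }
})

test_that("coefficients equal the normal-equations solution on the final basis", {
  for (seed in c(3, 8)) {
    d <- random_dataset(seed)
    f <- fit_mars(d)
    B <- cbind(1, vapply(seq_len(nrow(f$model$terms)), function(j) {
      hinge(d$age_weeks, f$model$terms$knot[j], f$model$terms$direction[j])
    }, numeric(nrow(d))))
    beta <- solve(crossprod(B), crossprod(B, d$weight_g))
    expect_equal(c(f$model$intercept, f$model$terms$coefficient),
                 as.numeric(beta), tolerance = 1e-6)
  }
})

test_that("predictions are continuous in age", {
  f <- fit_mars(weekly, prune = FALSE)
  grid <- seq(0, 6, by = 1e-3)
  w <- predict(f$model, grid)
  lipschitz <- sum(abs(f$model$terms$coefficient)) + 1
  expect_lt(max(abs(diff(w))), lipschitz * 1e-3 * 1.01)
})

test_that("max_terms = 1 yields the intercept-only model", {
  f <- fit_mars(weekly, max_terms = 1)
  expect_equal(f$model$n_basis, 1L)
  expect_equal(f$model$intercept, mean(weekly$weight_g))
  n <- nrow(weekly)
  rss <- sum((weekly$weight_g - mean(weekly$weight_g))^2)
  expect_equal(f$model$gcv, (rss / n) / (1 - 1 / n)^2)
})

test_that("too few distinct ages is an error", {
  d <- tibble::tibble(age_weeks = c(0, 0, 1, 1), weight_g = c(50, 55, 150, 160))
  expect_error(fit_mars(d), class = "flockfit_insufficient_data")
})

test_that("a random candidate-knot grid is seeded and reproducible", {
  f1 <- fit_mars(weekly, knots = "random", seed = 7)
  f2 <- fit_mars(weekly, knots = "random", seed = 7)
  expect_identical(f1$model$terms, f2$model$terms)
})

test_that("MARS models round-trip through JSON", {
  m <- published_hinge_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$terms, m$terms)
  expect_equal(predict(m2, 0:6), predict(m, 0:6))
})
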