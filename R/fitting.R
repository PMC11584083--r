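#' Control settings for nonlinear least-squares fitting
#'
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol Relative reduction in the sum of squares below which a start is
#'   declared converged.
#' @param gtol Gradient (cosine) tolerance for convergence.
#' @param n_starts Number of seeded multiplicative perturbations of the
#'   deterministic initial values tried in addition to the initial values
#'   themselves. Weibull and Hossfeld likelihoods are flat and correlated on
#'   few-point datasets, so a handful of restarts is cheap insurance.
#' @param perturb Maximum multiplicative perturbation factor: each start
#'   multiplies every parameter by `exp(U(-log(perturb), log(perturb)))`.
#' @param seed Integer seed controlling the perturbations; identical data,
#'   control and seed give bit-identical fits.
#' @param weighted If `TRUE`, minimise relative (weight-proportional)
#'   residuals instead of ordinary ones. Off by default: ordinary least
#'   squares on the weights is the documented loss.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(max_iter = 500, ftol = 1e-10, gtol = 1e-8,
                        n_starts = 8, perturb = 3, seed = 1L,
                        weighted = FALSE) {
  stopifnot(max_iter >= 1, ftol > 0, gtol > 0, n_starts >= 0, perturb >= 1)
  structure(list(max_iter = as.integer(max_iter), ftol = ftol, gtol = gtol,
                 n_starts = as.integer(n_starts), perturb = perturb,
                 seed = as.integer(seed), weighted = isTRUE(weighted)),
            class = "fit_control")
}

.validate_growth_data <- function(data, family = NULL, for_fitting = TRUE) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  need <- c("age_weeks", "weight_g")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("`data` must contain columns: ", paste(need, collapse = ", "),
         " (missing: ", paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  d <- tibble::tibble(age_weeks = as.numeric(data$age_weeks),
                      weight_g = as.numeric(data$weight_g))
  if (nrow(d) == 0) stop("`data` has no records", call. = FALSE)
  if (anyNA(d)) stop("`data` contains missing ages or weights", call. = FALSE)
  if (any(d$weight_g <= 0)) stop("all weights must be > 0", call. = FALSE)
  if (any(d$age_weeks < 0)) stop("all ages must be >= 0", call. = FALSE)
  if (for_fitting) {
    npar <- if (is.null(family)) 3L else length(.family_params[[family]])
    if (length(unique(d$age_weeks)) < npar + 1) {
      .insufficient(sprintf(
        "fitting a %d-parameter model needs at least %d distinct ages (got %d)",
        npar, npar + 1, length(unique(d$age_weeks))))
    }
    if (diff(range(d$weight_g)) == 0) {
      .insufficient("weights are constant; no growth signal to fit")
    }
  }
  d
}

.insufficient <- function(msg) {
  stop(structure(class = c("flockfit_insufficient_data", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Box bounds that keep every parameter in the domain where the curve is a
# growth curve and the inflection formulas stay defined.
.fit_bounds <- function(family, max_w) {
  b <- switch(family,
    logistic = ,
    gompertz = ,
    von_bertalanffy = list(
      lower = c(A = max_w * (1 + 1e-8), b = 1e-6, k = 1e-6),
      upper = c(A = 50 * max_w, b = 1e6, k = 10)),
    weibull = list(
      lower = c(A = max_w * (1 + 1e-8), b = 1e-6, k = 1e-6, lambda = 1 + 1e-3),
      upper = c(A = 50 * max_w, b = 50 * max_w, k = 10, lambda = 10)),
    hossfeld = list(
      lower = c(A = max_w * (1 + 1e-8), b1 = 1 + 1e-3, b2 = 1 + 1e-3),
      upper = c(A = 50 * max_w, b1 = 1e4, b2 = 10))
  )
  b
}

.clamp <- function(p, bounds) {
  pmin(pmax(p, bounds$lower * (1 + 1e-9)), bounds$upper * (1 - 1e-9))
}

# Least-squares slope/intercept of y on x; NULL when degenerate.
.loglin <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2 || diff(range(x[ok])) == 0) return(NULL)
  cf <- stats::coef(stats::lm.fit(cbind(1, x[ok]), y[ok]))
  list(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Deterministic initial parameter values
#'
#' Produces starting values for [fit_growth()]: the asymptote starts at 1.2
#' times the largest observed weight, the rate and size parameters come from a
#' log-linearisation of the family (each family is linear in `log` space once
#' `A` is fixed), and shape parameters fall back to mild defaults when the
#' linearisation is degenerate.
#'
#' @param data Data frame with columns `age_weeks` and `weight_g`.
#' @param family Model family name.
#' @return A [growth_params()] object inside the fitting bounds.
#' @export
initial_growth_values <- function(data, family) {
  family <- .check_family(family)
  d <- .validate_growth_data(data, family)
  w <- d$weight_g; t <- d$age_weeks
  A0 <- 1.2 * max(w)
  bounds <- .fit_bounds(family, max(w))
  eps <- 1e-9
  p0 <- switch(family,
    logistic = {
      z <- log(pmax(A0 / w - 1, eps))
      f <- .loglin(t, z)
      c(A = A0,
        b = if (is.null(f)) max(A0 / w[which.min(t)] - 1, eps) else exp(f$intercept),
        k = if (is.null(f)) 0.5 else max(-f$slope, 1e-4))
    },
    gompertz = {
      z <- log(pmax(-log(pmin(w / A0, 1 - eps)), eps))
      f <- .loglin(t, z)
      c(A = A0,
        b = if (is.null(f)) max(-log(w[which.min(t)] / A0), eps) else exp(f$intercept),
        k = if (is.null(f)) 0.5 else max(-f$slope, 1e-4))
    },
    weibull = {
      lam0 <- 2
      z <- log(pmax(A0 - w, eps))
      f <- .loglin(t^lam0, z)
      c(A = A0,
        b = if (is.null(f)) max(A0 - w[which.min(t)], eps) else exp(f$intercept),
        k = if (is.null(f)) 0.1 else max(-f$slope, 1e-5),
        lambda = lam0)
    },
    hossfeld = {
      pos <- t > 0
      f <- if (sum(pos) >= 2) .loglin(log(t[pos]), log(pmax(A0 / w[pos] - 1, eps))) else NULL
      c(A = A0,
        b1 = if (is.null(f)) 10 else exp(f$intercept),
        b2 = if (is.null(f)) 2 else -f$slope)
    },
    von_bertalanffy = {
      z <- log(pmax(1 - (w / A0)^(1 / 3), eps))
      f <- .loglin(t, z)
      c(A = A0,
        b = if (is.null(f)) 0.9 else exp(f$intercept),
        k = if (is.null(f)) 0.5 else max(-f$slope, 1e-4))
    }
  )
  p0 <- .clamp(p0, bounds)
  structure(list(family = family, params = p0), class = "growth_params")
}

#' Fit one growth-model family by nonlinear least squares
#'
#' Minimises the (optionally weighted) sum of squared residuals with
#' Levenberg-Marquardt under box bounds, starting from
#' [initial_growth_values()] plus `n_starts` seeded log-uniform perturbations,
#' and keeps the best converged solution. The objective never exceeds the
#' objective at the deterministic initial point.
#'
#' @param data Data frame with columns `age_weeks`, `weight_g` (and optionally
#'   `id`; ignored by the loss, which pools all records).
#' @param family Model family name; see [growth_families()].
#' @param control A [fit_control()] object.
#' @param start Optional [growth_params()] overriding the deterministic
#'   initial values (e.g. to restart from a previous fit).
#' @return An object of class `growth_fit`: fitted `params`, a `predictions`
#'   tibble (`age_weeks`, `observed`, `fitted`), `gof` (see [compute_gof()]),
#'   `inflection` (`NULL` when undefined), `sse`, `converged`,
#'   `n_starts_used`, and optimizer diagnostics.
#' @examples
#' fit <- fit_growth(broiler_weekly_weights(), "gompertz")
#' glance(fit)
#' @export
fit_growth <- function(data, family, control = fit_control(), start = NULL) {
  family <- .check_family(family)
  stopifnot(inherits(control, "fit_control"))
  d <- .validate_growth_data(data, family)
  if (is.null(start)) {
    start <- initial_growth_values(d, family)
  } else {
    stopifnot(inherits(start, "growth_params"), start$family == family)
  }
  bounds <- .fit_bounds(family, max(d$weight_g))
  p0 <- .clamp(start$params, bounds)

  starts <- list(p0)
  if (control$n_starts > 0) {
    withr::with_seed(control$seed, {
      for (i in seq_len(control$n_starts)) {
        f <- exp(stats::runif(length(p0), -log(control$perturb), log(control$perturb)))
        starts[[i + 1]] <- .clamp(p0 * f, bounds)
      }
    })
  }

  resid_fn <- function(par) {
    names(par) <- names(p0)
    pred <- .eval_family(family, par, d$age_weeks)
    r <- d$weight_g - pred
    if (control$weighted) r / pmax(abs(pred), 1) else r
  }

  best <- NULL
  best_any <- NULL  # best attempt even if not converged
  for (s in starts) {
    lm_fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = bounds$lower, upper = bounds$upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = control$max_iter, ftol = control$ftol,
          gtol = control$gtol, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(lm_fit)) next
    obj <- sum(lm_fit$fvec^2)
    conv <- lm_fit$info %in% 1:4
    cand <- list(par = stats::setNames(as.numeric(lm_fit$par), names(p0)),
                 obj = obj, converged = conv, info = lm_fit$info,
                 message = lm_fit$message, niter = lm_fit$niter)
    if (is.null(best_any) || obj < best_any$obj) best_any <- cand
    if (conv && (is.null(best) || obj < best$obj)) best <- cand
  }

  if (is.null(best)) {
    cond <- structure(
      class = c("flockfit_no_convergence", "error", "condition"),
      list(message = sprintf("no start converged when fitting the %s model", family),
           call = sys.call(), best_attempt = best_any))
    stop(cond)
  }

  params <- do.call(growth_params, c(list(family = family), as.list(best$par)))
  fitted <- growth_curve(params, d$age_weeks)
  sse <- sum((d$weight_g - fitted)^2)
  infl <- tryCatch(inflection(params),
                   flockfit_no_inflection = function(e) NULL)
  structure(list(
    family = family,
    params = params,
    start = start,
    predictions = tibble::tibble(age_weeks = d$age_weeks,
                                 observed = d$weight_g, fitted = fitted),
    gof = compute_gof(d$weight_g, fitted, k = length(p0)),
    inflection = infl,
    sse = sse,
    objective = best$obj,
    converged = TRUE,
    n_starts_used = length(starts),
    info = best$info,
    message = best$message,
    niter = best$niter,
    control = control
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", x$family, "on", nrow(x$predictions), "records\n")
  print(round(x$params$params, 4))
  cat(sprintf("SSE %.4f  R2 %.5f  AIC %.3f  BIC %.3f\n",
              x$gof$sse, x$gof$r2, x$gof$aic, x$gof$bic))
  if (!is.null(x$inflection)) {
    cat(sprintf("inflection at %.3f weeks, %.3f g\n",
                x$inflection$ipt, x$inflection$ipw))
  }
  invisible(x)
}

#' Fit all five growth-model families to one dataset
#'
#' Runs [fit_growth()] for every family in the fixed order of
#' [growth_families()]. Per-family failures (non-convergence, insufficient
#' data) are recorded in the returned list rather than raised; an error is
#' thrown only when every family fails.
#'
#' @inheritParams fit_growth
#' @param families Character vector of family names (default: all five).
#' @return A named list of class `growth_fit_list` whose elements are
#'   `growth_fit` objects or, for failed families, `growth_fit_failure`
#'   records carrying the condition.
#' @examples
#' fits <- fit_growth_all(broiler_weekly_weights())
#' rank_models(fits, "aic")
#' @export
fit_growth_all <- function(data, families = growth_families()$family,
                           control = fit_control()) {
  families <- vapply(families, .check_family, character(1))
  out <- lapply(families, function(fam) {
    tryCatch(fit_growth(data, fam, control), error = function(e) {
      structure(list(family = fam, error = e), class = "growth_fit_failure")
    })
  })
  names(out) <- families
  if (all(vapply(out, inherits, logical(1), "growth_fit_failure"))) {
    msgs <- vapply(out, function(f) conditionMessage(f$error), character(1))
    stop("all families failed to fit:\n", paste("-", families, ":", msgs, collapse = "\n"),
         call. = FALSE)
  }
  structure(out, class = "growth_fit_list")
}

#' @export
print.growth_fit_list <- function(x, ...) {
  cat("<growth_fit_list> of", length(x), "families\n")
  print(glance(x))
  invisible(x)
}
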