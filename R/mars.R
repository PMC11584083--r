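#' Hinge (piecewise-linear) basis function
#'
#' The building block of a MARS model: `max(0, x - knot)` for direction
#' `"above"` and `max(0, knot - x)` for direction `"below"`. Zero on one side
#' of the knot, linear on the other, continuous everywhere.
#'
#' @param x Numeric vector (age in weeks).
#' @param knot Breakpoint (weeks).
#' @param direction `"above"` or `"below"`.
#' @return Numeric vector, elementwise non-negative.
#' @examples
#' hinge(5, 1, "above")  # 4
#' hinge(5, 3, "below")  # 0
#' @export
hinge <- function(x, knot, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (direction == "above") pmax(0, x - knot) else pmax(0, knot - x)
}

#' Construct a MARS model from explicit coefficients
#'
#' A MARS model is an intercept plus a sum of coefficient-weighted hinge
#' terms, \eqn{f(x) = \beta_0 + \sum_m \beta_m h_m(x)}. This constructor
#' builds one directly from known coefficients, e.g. a model reported by a
#' previous analysis; fitted models come from [fit_mars()].
#'
#' @param intercept Intercept \eqn{\beta_0} in grams.
#' @param terms A data frame with columns `knot` (weeks), `direction`
#'   (`"above"`/`"below"`) and `coefficient` (g per week); may be empty.
#' @param gcv Optional generalized cross-validation score (fitted models).
#' @return An object of class `mars_model`.
#' @examples
#' m <- mars_model(326.7385, tibble::tibble(
#'   knot = c(1, 3, 3, 4),
#'   direction = c("above", "below", "above", "above"),
#'   coefficient = c(130.654, -93.33294, 292.7998, 151.775)))
#' predict(m, 0:6)
#' @export
mars_model <- function(intercept, terms = NULL, gcv = NULL) {
  if (is.null(terms)) {
    terms <- tibble::tibble(knot = numeric(0), direction = character(0),
                            coefficient = numeric(0))
  }
  terms <- tibble::as_tibble(terms)
  need <- c("knot", "direction", "coefficient")
  if (!all(need %in% names(terms))) {
    stop("`terms` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  terms <- terms[need]
  if (nrow(terms) && !all(terms$direction %in% c("above", "below"))) {
    stop("`direction` must be 'above' or 'below'", call. = FALSE)
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  structure(list(intercept = as.numeric(intercept), terms = terms,
                 gcv = if (is.null(gcv)) NULL else as.numeric(gcv),
                 n_basis = nrow(terms) + 1L),
            class = "mars_model")
}

#' @export
print.mars_model <- function(x, ...) {
  cat("<mars_model> intercept", format(x$intercept), "+", nrow(x$terms),
      "hinge terms\n")
  if (nrow(x$terms)) print(x$terms)
  if (!is.null(x$gcv)) cat("GCV:", format(x$gcv), "\n")
  invisible(x)
}

.mars_basis <- function(x, terms) {
  B <- matrix(1, nrow = length(x), ncol = nrow(terms) + 1L)
  if (nrow(terms)) {
    for (j in seq_len(nrow(terms))) {
      B[, j + 1L] <- hinge(x, terms$knot[j], terms$direction[j])
    }
  }
  B
}

#' Predict from a MARS model
#'
#' @param object A [mars_model()].
#' @param newdata Numeric vector of ages (weeks), or a data frame with an
#'   `age_weeks` column.
#' @param ... Unused.
#' @return Numeric vector of predicted weights (g).
#' @export
predict.mars_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) as.numeric(newdata$age_weeks) else as.numeric(newdata)
  if (length(x) == 0) return(numeric(0))
  drop(.mars_basis(x, object$terms) %*% c(object$intercept, object$terms$coefficient))
}

#' Generalized cross-validation score
#'
#' `GCV = (RSS / n) / (1 - M / n)^2`, where `M` is the effective model size
#' (coefficients plus a per-knot penalty). It inflates the training error by
#' model complexity so that backward pruning can select a model without
#' held-out data.
#'
#' @param rss Residual sum of squares (g^2), non-negative.
#' @param n Number of training observations.
#' @param effective_terms Effective model size `M`; must be smaller than `n`.
#' @return The GCV score (g^2).
#' @examples
#' gcv(700, 7, 0)    # 100
#' gcv(700, 7, 3.5)  # 400
#' @export
gcv <- function(rss, n, effective_terms) {
  stopifnot(length(rss) == 1, length(n) == 1, length(effective_terms) == 1)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (rss < 0) stop("`rss` must be non-negative", call. = FALSE)
  if (effective_terms >= n) {
    stop(structure(class = c("flockfit_gcv_undefined", "error", "condition"),
                   list(message = sprintf(
                     "GCV undefined: effective model size (%.2f) must be below n (%d)",
                     effective_terms, as.integer(n)), call = sys.call())))
  }
  (rss / n) / (1 - effective_terms / n)^2
}

# Effective model size: one coefficient per basis function (incl. intercept)
# plus `penalty` per distinct knot.
.mars_effective_size <- function(terms, penalty) {
  (nrow(terms) + 1) + penalty * length(unique(terms$knot))
}

.gcv_or_inf <- function(rss, n, eff) {
  if (eff >= n) Inf else (rss / n) / (1 - eff / n)^2
}

# Exact linear least squares on basis B; NULL when B is rank deficient.
.ols <- function(B, y, tol = 1e-9) {
  qrB <- qr(B, tol = tol)
  if (qrB$rank < ncol(B)) return(NULL)
  coef <- qr.coef(qrB, y)
  fitted <- drop(B %*% coef)
  list(coef = coef, fitted = fitted, rss = sum((y - fitted)^2))
}

#' Fit a single-predictor MARS model
#'
#' Greedy forward selection of hinge terms followed by GCV-guided backward
#' pruning. At each forward step every candidate knot is examined; the
#' reflected hinge pair at that knot (or a single hinge, when its mirror is
#' collinear with the current basis or there is no room) that most reduces
#' the training RSS is added, with coefficients refit by exact linear least
#' squares at every step. Ties in RSS are broken by the smaller knot, then by
#' direction (pair, then `"above"`, then `"below"`), so fits are
#' deterministic. The backward pass deletes one term at a time (the deletion
#' that least increases RSS) and the model with the smallest GCV along the
#' deletion sequence is returned.
#'
#' @param data Data frame with columns `age_weeks` and `weight_g`; at least
#'   three distinct ages are required.
#' @param max_terms Maximum number of basis functions, counting the
#'   intercept; `max_terms = 1` fits the intercept-only model.
#' @param penalty Per-knot complexity charge `d` in the effective model size
#'   used by GCV (coefficients + d x knots). `d = 2` is the usual additive-
#'   model convention.
#' @param minspan Minimum number of distinct observed ages (inclusive of the
#'   candidate) between a candidate knot and any knot already in the model;
#'   `1` imposes no restriction.
#' @param prune If `FALSE`, skip backward pruning and return the full forward
#'   model.
#' @param knots `"observed"` places candidate knots at the distinct observed
#'   ages (deterministic default, natural for weekly weighings); `"random"`
#'   draws `n_candidates` uniform locations within the age range.
#' @param n_candidates Number of random candidate knots when
#'   `knots = "random"`.
#' @param seed Seed for the random candidate grid.
#' @return An object of class `mars_fit` with elements `model`
#'   ([mars_model()] with its GCV), `fitted`, `rss`, `r2`, `forward` (per-step
#'   trace) and `prune_path` (deletion-sequence trace).
#' @examples
#' fit <- fit_mars(broiler_weekly_weights())
#' fit$model
#' @export
fit_mars <- function(data, max_terms = 21, penalty = 2, minspan = 1,
                     prune = TRUE, knots = c("observed", "random"),
                     n_candidates = NULL, seed = 1L) {
  knots <- match.arg(knots)
  d <- .validate_growth_data(data, for_fitting = FALSE)
  x <- d$age_weeks; y <- d$weight_g
  ux <- sort(unique(x))
  if (length(ux) < 3) .insufficient("MARS fitting needs at least 3 distinct ages")
  stopifnot(max_terms >= 1, penalty >= 0, minspan >= 1)
  n <- length(y)

  candidates <- if (knots == "observed") ux else {
    nc <- if (is.null(n_candidates)) 2L * length(ux) else as.integer(n_candidates)
    withr::with_seed(seed, sort(stats::runif(nc, min(ux), max(ux))))
  }

  max_coef <- min(max_terms, n)
  terms <- mars_model(0)$terms  # empty terms tibble
  fit_cur <- .ols(matrix(1, n, 1), y)
  rss_tot <- sum((y - mean(y))^2)
  forward_trace <- list(tibble::tibble(step = 0L, knot = NA_real_,
                                       addition = "intercept", rss = fit_cur$rss))
  step <- 0L

  # a candidate knot must keep >= minspan - 1 distinct ages strictly between
  # itself and every knot already in the model
  eligible_knot <- function(t) {
    if (minspan == 1 || nrow(terms) == 0) return(TRUE)
    all(vapply(unique(terms$knot), function(u) {
      between <- sum(ux > min(t, u) & ux < max(t, u))
      t != u && between >= minspan - 1
    }, logical(1)))
  }

  repeat {
    if (nrow(terms) + 1L >= max_coef) break
    room_pair <- nrow(terms) + 3L <= max_coef
    best <- NULL
    for (t in candidates) {
      if (!eligible_knot(t)) next
      have <- terms$direction[terms$knot == t]
      free <- setdiff(c("above", "below"), have)
      if (!length(free)) next
      additions <- list()
      if (room_pair && length(free) == 2) {
        additions <- c(additions, list(list(dirs = c("above", "below"), what = "pair")))
      }
      for (dir in free) additions <- c(additions, list(list(dirs = dir, what = dir)))
      for (add in additions) {
        new_terms <- dplyr::bind_rows(
          terms[c("knot", "direction")],
          tibble::tibble(knot = t, direction = add$dirs))
        B <- .mars_basis(x, new_terms)
        f <- .ols(B, y)
        if (is.null(f)) next  # rank-deficient basis: drop this addition
        prio <- match(add$what, c("pair", "above", "below"))
        if (is.null(best) ||
            f$rss < best$rss - 1e-12 ||
            (abs(f$rss - best$rss) <= 1e-12 &&
             (t < best$knot || (t == best$knot && prio < best$prio)))) {
          best <- list(knot = t, what = add$what, dirs = add$dirs,
                       rss = f$rss, fit = f, terms = new_terms, prio = prio)
        }
      }
    }
    if (is.null(best)) break
    step <- step + 1L
    terms <- best$terms
    terms$coefficient <- as.numeric(best$fit$coef[-1])
    fit_cur <- best$fit
    forward_trace[[step + 1L]] <- tibble::tibble(
      step = step, knot = best$knot, addition = best$what, rss = best$rss)
    if (best$rss <= 1e-12 * (rss_tot + 1)) break
  }
  forward <- dplyr::bind_rows(forward_trace)

  refit <- function(tm) {
    f <- .ols(.mars_basis(x, tm), y)
    stopifnot(!is.null(f))
    f
  }

  # backward pass: deletion sequence down to the intercept-only model
  seq_list <- list(list(terms = terms, fit = fit_cur))
  cur <- terms
  while (nrow(cur) > 0) {
    rss_drop <- vapply(seq_len(nrow(cur)), function(i) {
      f <- .ols(.mars_basis(x, cur[-i, , drop = FALSE]), y)
      if (is.null(f)) Inf else f$rss
    }, numeric(1))
    j <- which.min(rss_drop)
    cur <- cur[-j, , drop = FALSE]
    seq_list[[length(seq_list) + 1L]] <- list(terms = cur, fit = refit(cur))
  }
  prune_path <- dplyr::bind_rows(lapply(seq_along(seq_list), function(i) {
    s <- seq_list[[i]]
    eff <- .mars_effective_size(s$terms, penalty)
    tibble::tibble(step = i - 1L, n_terms = nrow(s$terms), rss = s$fit$rss,
                   effective_size = eff, gcv = .gcv_or_inf(s$fit$rss, n, eff))
  }))

  sel <- if (prune) {
    cand <- which(prune_path$gcv == min(prune_path$gcv))
    max(cand)  # tie: prefer the smaller model (later in the deletion sequence)
  } else 1L
  chosen <- seq_list[[sel]]
  chosen_terms <- chosen$terms
  if (nrow(chosen_terms)) {
    chosen_terms$coefficient <- as.numeric(chosen$fit$coef[-1])
  }
  model <- mars_model(intercept = as.numeric(chosen$fit$coef[1]),
                      terms = chosen_terms,
                      gcv = prune_path$gcv[sel])
  fitted <- chosen$fit$fitted
  structure(list(
    model = model,
    data = d,
    fitted = fitted,
    residuals = y - fitted,
    rss = chosen$fit$rss,
    r2 = 1 - chosen$fit$rss / rss_tot,
    forward = forward,
    prune_path = prune_path,
    pruned = prune,
    config = list(max_terms = max_terms, penalty = penalty, minspan = minspan,
                  knots = knots, seed = seed)
  ), class = "mars_fit")
}

#' @export
print.mars_fit <- function(x, ...) {
  cat("<mars_fit> on", nrow(x$data), "records\n")
  print(x$model)
  cat(sprintf("RSS %.4f  R2 %.5f\n", x$rss, x$r2))
  invisible(x)
}

#' @export
predict.mars_fit <- function(object, newdata = object$data, ...) {
  predict(object$model, newdata)
}
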