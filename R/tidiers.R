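#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted growth model
#'
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `family`, `term`, `estimate`.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(family = x$family,
                 term = names(x$params$params),
                 estimate = unname(x$params$params))
}

#' One-row summary of a fitted growth model
#'
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: family, goodness-of-fit criteria, inflection
#'   point (`ipt`, `ipw`; `NA` when undefined) and convergence diagnostics.
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(family = x$family),
    x$gof,
    tibble::tibble(
      ipt = if (is.null(x$inflection)) NA_real_ else x$inflection$ipt,
      ipw = if (is.null(x$inflection)) NA_real_ else x$inflection$ipw,
      converged = x$converged,
      n_starts_used = x$n_starts_used)
  )
}

#' Observation-level results of a growth fit
#'
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @return The `predictions` tibble with a `.resid` column appended.
#' @method augment growth_fit
#' @export
augment.growth_fit <- function(x, ...) {
  dplyr::mutate(x$predictions, .resid = .data$observed - .data$fitted)
}

#' @method tidy growth_fit_list
#' @export
tidy.growth_fit_list <- function(x, ...) {
  dplyr::bind_rows(lapply(.fit_list_ok(x), tidy))
}

#' @method glance growth_fit_list
#' @export
glance.growth_fit_list <- function(x, ...) {
  rows <- lapply(x, function(f) {
    if (inherits(f, "growth_fit_failure")) {
      tibble::tibble(family = f$family, converged = FALSE,
                     failure = conditionMessage(f$error))
    } else {
      glance(f)
    }
  })
  dplyr::bind_rows(rows)
}

.fit_list_ok <- function(x) {
  Filter(function(f) inherits(f, "growth_fit"), x)
}

#' Tidy a fitted MARS model
#'
#' @param x A `mars_fit` or `mars_model` object.
#' @param ... Unused.
#' @return A tibble with one row per basis function (`"intercept"` first):
#'   `term`, `knot`, `direction`, `estimate`.
#' @method tidy mars_fit
#' @export
tidy.mars_fit <- function(x, ...) tidy(x$model)

#' @method tidy mars_model
#' @export
tidy.mars_model <- function(x, ...) {
  hinge_lab <- function(knot, direction) {
    ifelse(direction == "above",
           sprintf("max(0, age - %g)", knot),
           sprintf("max(0, %g - age)", knot))
  }
  dplyr::bind_rows(
    tibble::tibble(term = "intercept", knot = NA_real_,
                   direction = NA_character_, estimate = x$intercept),
    if (nrow(x$terms)) tibble::tibble(
      term = hinge_lab(x$terms$knot, x$terms$direction),
      knot = x$terms$knot, direction = x$terms$direction,
      estimate = x$terms$coefficient)
  )
}

#' One-row summary of a MARS fit
#'
#' @param x A `mars_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_basis`, `rss`, `r2`, `gcv`, `pruned`.
#' @method glance mars_fit
#' @export
glance.mars_fit <- function(x, ...) {
  tibble::tibble(n = nrow(x$data), n_basis = x$model$n_basis,
                 rss = x$rss, r2 = x$r2, gcv = x$model$gcv, pruned = x$pruned)
}
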