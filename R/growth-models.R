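#' Supported growth-model families
#'
#' Weekly body weight of a broiler follows a sigmoidal trajectory from hatch
#' weight towards a mature asymptote `A`. Five classical parameterisations of
#' that trajectory are supported:
#'
#' * **logistic**: \eqn{Y(t) = A / (1 + b e^{-kt})}
#' * **gompertz**: \eqn{Y(t) = A \exp(-b e^{-kt})}
#' * **weibull**: \eqn{Y(t) = A - b \exp(-k t^{\lambda})}
#' * **hossfeld**: \eqn{Y(t) = A (1 + b_1 t^{-b_2})^{-1}}
#' * **von_bertalanffy**: \eqn{Y(t) = A (1 - b e^{-kt})^3}
#'
#' Units are fixed package-wide: age `t` in weeks, weight in grams.
#'
#' @return A tibble with one row per family: `family`, `n_params` and a
#'   list-column `param_names` giving the ordered parameter labels.
#' @examples
#' growth_families()
#' @export
growth_families <- function() {
  tibble::tibble(
    family = names(.family_params),
    n_params = lengths(.family_params),
    param_names = unname(.family_params)
  )
}

.family_params <- list(
  logistic        = c("A", "b", "k"),
  gompertz        = c("A", "b", "k"),
  weibull         = c("A", "b", "k", "lambda"),
  hossfeld        = c("A", "b1", "b2"),
  von_bertalanffy = c("A", "b", "k")
)

.family_names <- function() names(.family_params)

.check_family <- function(family) {
  if (!is.character(family) || length(family) != 1 || !family %in% .family_names()) {
    stop("`family` must be one of: ", paste(.family_names(), collapse = ", "),
         call. = FALSE)
  }
  family
}

#' Construct a validated growth-model parameter set
#'
#' @param family One of `"logistic"`, `"gompertz"`, `"weibull"`, `"hossfeld"`,
#'   `"von_bertalanffy"`.
#' @param A Asymptotic (mature) weight in grams; must be positive.
#' @param b Initial-size parameter (dimensionless for logistic, Gompertz and
#'   von Bertalanffy; grams for Weibull, where `A - b` is the hatch weight).
#' @param k Rate constant per week; must be positive.
#' @param lambda Weibull shape parameter; must be positive. An inflection
#'   exists only for `lambda > 1`.
#' @param b1,b2 Hossfeld shape parameters; `b1 > 1` and `b2 > 0` are required,
#'   and the inflection exists only for `b2 > 1`.
#'
#' @return An object of class `growth_params`: a list with elements `family`
#'   and a named numeric vector `params`.
#' @examples
#' growth_params("gompertz", A = 6854.354, b = 4.882, k = 0.241)
#' @export
growth_params <- function(family, A, b = NULL, k = NULL, lambda = NULL,
                          b1 = NULL, b2 = NULL) {
  family <- .check_family(family)
  supplied <- list(A = A, b = b, k = k, lambda = lambda, b1 = b1, b2 = b2)
  wanted <- .family_params[[family]]
  missing <- wanted[vapply(supplied[wanted], is.null, logical(1))]
  if (length(missing)) {
    stop(sprintf("family '%s' requires parameters: %s (missing: %s)", family,
                 paste(wanted, collapse = ", "), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(names(supplied)[!vapply(supplied, is.null, logical(1))], wanted)
  if (length(extra)) {
    stop(sprintf("parameters not defined for family '%s': %s", family,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  p <- vapply(supplied[wanted], function(v) as.numeric(v)[1], numeric(1))
  .check_param_domain(family, p)
  structure(list(family = family, params = p), class = "growth_params")
}

.check_param_domain <- function(family, p) {
  bad <- function(msg) stop("invalid parameters for family '", family, "': ",
                            msg, call. = FALSE)
  if (!all(is.finite(p))) bad("all parameters must be finite")
  if (p[["A"]] <= 0) bad("A must be > 0")
  if ("k" %in% names(p) && p[["k"]] <= 0) bad("k must be > 0")
  if ("b" %in% names(p) && p[["b"]] <= 0) bad("b must be > 0")
  if ("lambda" %in% names(p) && p[["lambda"]] <= 0) bad("lambda must be > 0")
  if ("b1" %in% names(p) && p[["b1"]] <= 1) bad("b1 must be > 1")
  if ("b2" %in% names(p) && p[["b2"]] <= 0) bad("b2 must be > 0")
  invisible(p)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>", x$family, "\n")
  print(round(x$params, 6))
  invisible(x)
}

#' Evaluate a growth curve at given ages
#'
#' Vectorised closed-form evaluation of the family's mean trajectory. All
#' families approach the asymptote `A` as age grows. The Hossfeld form
#' contains `t^(-b2)`, which diverges at `t = 0`; the curve is extended there
#' by its continuity limit, `Y(0) = 0`.
#'
#' @param params A [growth_params()] object.
#' @param ages Numeric vector of ages in weeks; must be non-negative.
#' @return Numeric vector of predicted weights in grams, same length as `ages`.
#' @examples
#' p <- growth_params("logistic", A = 3136.722, b = 37.106, k = 0.736)
#' growth_curve(p, 0:6)
#' @export
growth_curve <- function(params, ages) {
  stopifnot(inherits(params, "growth_params"))
  ages <- as.numeric(ages)
  if (length(ages) == 0) return(numeric(0))
  if (anyNA(ages) || any(ages < 0)) {
    stop("`ages` must be non-negative and non-missing", call. = FALSE)
  }
  .eval_family(params$family, params$params, ages)
}

# Closed-form evaluation on a raw named parameter vector (no domain checks);
# shared by growth_curve() and the least-squares residual function.
.eval_family <- function(family, p, ages) {
  switch(family,
    logistic = p[["A"]] / (1 + p[["b"]] * exp(-p[["k"]] * ages)),
    gompertz = p[["A"]] * exp(-p[["b"]] * exp(-p[["k"]] * ages)),
    weibull  = p[["A"]] - p[["b"]] * exp(-p[["k"]] * ages^p[["lambda"]]),
    hossfeld = {
      # t^(-b2) -> Inf as t -> 0+, so A/(1 + b1 t^(-b2)) -> 0: define Y(0) = 0.
      out <- ifelse(ages == 0, 0,
                    p[["A"]] / (1 + p[["b1"]] * ages^(-p[["b2"]])))
      as.numeric(out)
    },
    von_bertalanffy = p[["A"]] * (1 - p[["b"]] * exp(-p[["k"]] * ages))^3
  )
}

#' Age and weight at the inflection point
#'
#' The inflection point is where the weekly growth rate is maximal and the
#' curve changes concavity. Each family has a closed form:
#'
#' * logistic: \eqn{t^* = \ln(b)/k}, \eqn{Y^* = A/2}
#' * gompertz: \eqn{t^* = \ln(b)/k}, \eqn{Y^* = A/e}
#' * weibull: \eqn{t^* = [(\lambda-1)/(k\lambda)]^{1/\lambda}},
#'   \eqn{Y^* = A - b e^{-(1 - 1/\lambda)}} (requires \eqn{\lambda > 1})
#' * hossfeld: \eqn{t^* = [b_1(b_2-1)/(b_2+1)]^{1/b_2}},
#'   \eqn{Y^* = A(b_2-1)/(2 b_2)} (requires \eqn{b_2 > 1})
#' * von_bertalanffy: \eqn{t^* = \ln(3b)/k}, \eqn{Y^* = 8A/27}
#'   (requires \eqn{3b \ge 1})
#'
#' When the parameters place the inflection at a negative age (e.g. logistic
#' with `b < 1`) or no inflection exists, an error of class
#' `flockfit_no_inflection` is signalled.
#'
#' @param params A [growth_params()] object.
#' @return A one-row tibble with columns `ipt` (weeks) and `ipw` (grams).
#' @examples
#' inflection(growth_params("gompertz", A = 6854.354, b = 4.882, k = 0.241))
#' @export
inflection <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  p <- params$params
  no_infl <- function(msg) {
    stop(structure(class = c("flockfit_no_inflection", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  res <- switch(params$family,
    logistic = c(log(p[["b"]]) / p[["k"]], p[["A"]] / 2),
    gompertz = c(log(p[["b"]]) / p[["k"]], p[["A"]] / exp(1)),
    weibull = {
      if (p[["lambda"]] <= 1) no_infl("Weibull curve has no inflection for lambda <= 1")
      lam <- p[["lambda"]]
      c(((lam - 1) / (p[["k"]] * lam))^(1 / lam),
        p[["A"]] - p[["b"]] * exp(-(1 - 1 / lam)))
    },
    hossfeld = {
      if (p[["b2"]] <= 1) no_infl("Hossfeld curve has no inflection for b2 <= 1")
      b1 <- p[["b1"]]; b2 <- p[["b2"]]
      c((b1 * (b2 - 1) / (b2 + 1))^(1 / b2),
        p[["A"]] * (b2 - 1) / (2 * b2))
    },
    von_bertalanffy = {
      if (3 * p[["b"]] < 1) no_infl("von Bertalanffy curve has no inflection at non-negative age for 3b < 1")
      c(log(3 * p[["b"]]) / p[["k"]], 8 * p[["A"]] / 27)
    }
  )
  if (res[1] < 0) {
    no_infl(sprintf("inflection of the %s curve lies at negative age (%.4f weeks)",
                    params$family, res[1]))
  }
  tibble::tibble(ipt = res[1], ipw = res[2])
}
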