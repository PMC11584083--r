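#' Goodness-of-fit criteria for a model on one dataset
#'
#' Computes the criteria used to compare growth models: sum of squared errors
#' (SSE), mean squared error MSE = SSE/n, RMSE, the coefficient of
#' determination R^2 = 1 - SSE/SStot, adjusted R^2, and the least-squares
#' information criteria AIC = n log(SSE/n) + 2k and
#' BIC = n log(SSE/n) + k log(n), where `k` counts the curve parameters only.
#'
#' A degrees-of-freedom variant `mse_df = SSE/(n - k)` is reported alongside
#' `mse` (it is `NA` when `n <= k`). When the fit is exact (SSE = 0) the log
#' terms are -Inf; `aic` and `bic` are then reported as `-Inf` and the
#' `zero_sse` flag is set.
#'
#' @param observed,predicted Numeric vectors of equal, nonzero length (grams).
#' @param k Number of model parameters (>= 1).
#' @return A one-row tibble: `n`, `k`, `sse`, `mse`, `mse_df`, `rmse`, `r2`,
#'   `adj_r2`, `aic`, `bic`, `zero_sse`.
#' @examples
#' compute_gof(c(0, 2), c(1, 1), k = 1)
#' @export
compute_gof <- function(observed, predicted, k) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) == 0 || length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal nonzero length", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values in `observed` or `predicted`", call. = FALSE)
  }
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1) stop("`k` must be an integer >= 1", call. = FALSE)
  n <- length(observed)
  sse <- sum((observed - predicted)^2)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    stop("R^2 is undefined for a constant observed vector", call. = FALSE)
  }
  mse <- sse / n
  r2 <- 1 - sse / sstot
  adj_r2 <- if (n - k - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - k - 1) else NA_real_
  zero_sse <- sse == 0
  ll <- if (zero_sse) -Inf else n * log(sse / n)
  aic <- ll + 2 * k
  tibble::tibble(
    n = n, k = k,
    sse = sse, mse = mse,
    mse_df = if (n > k) sse / (n - k) else NA_real_,
    rmse = sqrt(mse),
    r2 = r2, adj_r2 = adj_r2,
    aic = aic,
    # computed from aic so that bic - aic = k(log n - 2) holds bitwise
    bic = aic + k * (log(n) - 2),
    zero_sse = zero_sse
  )
}

#' Rank competing models by a fit criterion
#'
#' Orders models ascending by `aic`, `bic` or `mse` and descending by `r2`.
#' Ties preserve the input order, so a deterministic input yields a
#' deterministic ranking.
#'
#' @param x Either a data frame with a `family` (or `model`) column and a
#'   column named after `criterion`, or a list of fits as returned by
#'   [fit_growth_all()].
#' @param criterion One of `"aic"`, `"bic"`, `"mse"`, `"r2"`.
#' @return A tibble ordered best-first with a `rank` column prepended.
#' @examples
#' tbl <- tibble::tibble(
#'   family = c("logistic", "gompertz", "weibull", "hossfeld", "von_bertalanffy"),
#'   aic = c(70.357, 68.750, 74.723, 78.934, 72.317)
#' )
#' rank_models(tbl, "aic")
#' @export
rank_models <- function(x, criterion = c("aic", "bic", "mse", "r2")) {
  criterion <- match.arg(criterion)
  if (inherits(x, "growth_fit_list")) x <- glance(x)
  if (inherits(x, "growth_fit")) x <- glance(x)
  if (!is.data.frame(x) || nrow(x) == 0) {
    stop("`x` must be a non-empty data frame (or fit list) carrying a '",
         criterion, "' column", call. = FALSE)
  }
  if (!criterion %in% names(x)) {
    stop("column '", criterion, "' not found", call. = FALSE)
  }
  v <- x[[criterion]]
  ord <- order(if (criterion == "r2") -v else v)  # radix sort: stable in ties
  out <- tibble::as_tibble(x)[ord, , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}
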