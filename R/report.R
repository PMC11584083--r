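#' Fit and compare all growth models and MARS on one dataset
#'
#' The full comparison pipeline: fits the five parametric families with
#' [fit_growth_all()], fits a MARS model with [fit_mars()], assembles the
#' three standard report tables (parameters; criteria with inflection point
#' and final predicted weight; per-age observed/predicted matrix) and ranks
#' the models.
#'
#' @param data Data frame with `age_weeks`, `weight_g` (and optionally `id`).
#' @param criterion Ranking criterion, see [rank_models()].
#' @param control A [fit_control()] object for the parametric fits.
#' @param mars_args Named list of extra arguments passed to [fit_mars()].
#' @return An object of class `growth_comparison` with elements `fits`,
#'   `mars`, `parameters`, `criteria`, `predictions`, `ranking`, `best`.
#' @examples
#' cmp <- compare_growth(broiler_weekly_weights())
#' cmp$criteria
#' @export
compare_growth <- function(data, criterion = c("aic", "bic", "mse", "r2"),
                           control = fit_control(), mars_args = list()) {
  criterion <- match.arg(criterion)
  d <- .validate_growth_data(data, for_fitting = FALSE)
  last_age <- max(d$age_weeks)
  fits <- fit_growth_all(d, control = control)
  mars <- tryCatch(do.call(fit_mars, c(list(data = d), mars_args)),
                   error = function(e) {
                     structure(list(family = "mars", error = e),
                               class = "growth_fit_failure")
                   })

  ok <- .fit_list_ok(fits)
  parameters <- tidy(fits) |>
    tidyr::pivot_wider(names_from = "term", values_from = "estimate")

  criteria_parametric <- purrr::map(ok, function(f) {
    dplyr::mutate(glance(f),
                  final_weight = growth_curve(f$params, last_age))
  }) |> dplyr::bind_rows()
  failed <- Filter(function(f) inherits(f, "growth_fit_failure"), fits)
  criteria_failed <- purrr::map(failed, function(f) {
    tibble::tibble(family = f$family, converged = FALSE,
                   failure = conditionMessage(f$error))
  }) |> dplyr::bind_rows()

  criteria_mars <- if (inherits(mars, "mars_fit")) {
    obs <- stats::aggregate(weight_g ~ age_weeks, data = d, FUN = mean)
    gof <- compute_gof(d$weight_g, mars$fitted, k = mars$model$n_basis)
    dplyr::bind_cols(tibble::tibble(family = "mars"), gof,
                     tibble::tibble(ipt = NA_real_, ipw = NA_real_,
                                    converged = TRUE, n_starts_used = NA_integer_,
                                    final_weight = predict(mars$model, last_age)))
  } else {
    tibble::tibble(family = "mars", converged = FALSE,
                   failure = conditionMessage(mars$error))
  }
  criteria <- dplyr::bind_rows(criteria_parametric, criteria_mars, criteria_failed)

  # per-age observed/predicted matrix (one column per model)
  ages <- sort(unique(d$age_weeks))
  observed <- vapply(ages, function(a) mean(d$weight_g[d$age_weeks == a]),
                     numeric(1))
  predictions <- tibble::tibble(age_weeks = ages, observed = observed)
  for (f in ok) predictions[[f$family]] <- growth_curve(f$params, ages)
  if (inherits(mars, "mars_fit")) predictions$mars <- predict(mars$model, ages)

  rankable <- criteria[!is.na(criteria[[criterion]]), , drop = FALSE]
  ranking <- rank_models(rankable, criterion)
  structure(list(fits = fits, mars = mars, parameters = parameters,
                 criteria = criteria, predictions = predictions,
                 ranking = ranking, criterion = criterion,
                 best = ranking$family[1]),
            class = "growth_comparison")
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat("<growth_comparison> best by", x$criterion, "->", x$best, "\n\n")
  print(dplyr::select(x$criteria, dplyr::any_of(
    c("family", "r2", "adj_r2", "mse", "rmse", "aic", "bic", "ipt", "ipw",
      "final_weight"))))
  invisible(x)
}

.round_cols <- function(df, digits, except = character(0)) {
  num <- vapply(df, is.numeric, logical(1)) & !names(df) %in% except
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write a comparison report to disk
#'
#' Emits `parameters.csv`, `criteria.csv`, `predictions.csv`, a JSON bundle
#' `report.json`, and a curve-overlay figure `curves.png`. Parameters and
#' criteria are printed with 3 decimals and weights with 2 (round-half-even),
#' so repeated runs on identical inputs produce byte-identical tables.
#'
#' @param x A `growth_comparison` object.
#' @param dir Output directory (created if needed).
#' @param figure Write `curves.png`? Defaults to `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_growth_report <- function(x, dir, figure = TRUE) {
  stopifnot(inherits(x, "growth_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(.round_cols(x$parameters, 3),
                   file.path(dir, "parameters.csv"))
  readr::write_csv(
    .round_cols(.round_cols(x$criteria, 2, except = setdiff(names(x$criteria),
                                                            c("final_weight", "ipw"))), 3),
    file.path(dir, "criteria.csv"))
  readr::write_csv(.round_cols(x$predictions, 2),
                   file.path(dir, "predictions.csv"))
  bundle <- list(
    best = x$best, criterion = x$criterion,
    parameters = x$parameters, criteria = x$criteria,
    predictions = x$predictions, ranking = x$ranking)
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, null = "null")
  if (figure) {
    ggplot2::ggsave(file.path(dir, "curves.png"), autoplot(x),
                    width = 7, height = 5, dpi = 150)
  }
  invisible(dir)
}

#' End-to-end comparison run from a CSV file
#'
#' Reads age-weight records, fits the five growth models and MARS, and (when
#' `out_dir` is given) writes the report files. Per-family fit failures are
#' recorded in the criteria table; only a total failure raises an error.
#'
#' @param input_csv Path to a CSV in the dialect of [read_growth_csv()].
#' @param out_dir Optional output directory for [write_growth_report()].
#' @param criterion Ranking criterion.
#' @param seed Seed for the multi-start fitting perturbations.
#' @param figure Passed to [write_growth_report()].
#' @return The `growth_comparison` object, invisibly.
#' @export
run_compare <- function(input_csv, out_dir = NULL,
                        criterion = c("aic", "bic", "mse", "r2"),
                        seed = 1L, figure = TRUE) {
  criterion <- match.arg(criterion)
  data <- read_growth_csv(input_csv)
  cmp <- compare_growth(data, criterion = criterion,
                        control = fit_control(seed = seed),
                        mars_args = list(seed = seed))
  if (!is.null(out_dir)) write_growth_report(cmp, out_dir, figure = figure)
  invisible(cmp)
}

#' Predict weights from a serialized model
#'
#' @param model_json Path to a model JSON document (growth model or MARS; see
#'   [read_model_json()]).
#' @param ages Numeric vector of ages in weeks (may be empty).
#' @param out_csv Optional path; when given, the prediction table is written
#'   there (header-only for an empty age vector).
#' @return A tibble with columns `age_weeks` and `predicted_weight_g`.
#' @export
run_predict <- function(model_json, ages, out_csv = NULL) {
  model <- read_model_json(model_json)
  ages <- as.numeric(ages)
  pred <- if (inherits(model, "growth_params")) {
    growth_curve(model, ages)
  } else {
    predict(model, ages)
  }
  out <- tibble::tibble(age_weeks = ages, predicted_weight_g = pred)
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}

#' Simulate a flock from a scenario file
#'
#' @param scenario_json Path to a scenario JSON document.
#' @param out_csv Optional path for the simulated records.
#' @return The simulated tibble.
#' @export
run_simulate <- function(scenario_json, out_csv = NULL) {
  sim <- simulate_scenario(read_scenario_json(scenario_json))
  if (!is.null(out_csv)) readr::write_csv(sim, out_csv)
  sim
}
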