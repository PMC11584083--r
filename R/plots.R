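#' Plot a fitted growth curve over the data
#'
#' @param object A `growth_fit` object.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, n_grid = 200, ...) {
  grid <- seq(min(object$predictions$age_weeks),
              max(object$predictions$age_weeks), length.out = n_grid)
  curve <- tibble::tibble(age_weeks = grid,
                          weight_g = growth_curve(object$params, grid))
  ggplot2::ggplot(object$predictions, ggplot2::aes(x = .data$age_weeks)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$weight_g),
                       colour = "steelblue") +
    ggplot2::labs(x = "Age (weeks)", y = "Body weight (g)",
                  title = paste("Fitted", object$family, "growth curve")) +
    ggplot2::theme_minimal()
}

#' Plot a MARS fit: data, knots and the piecewise-linear prediction
#'
#' @param object A `mars_fit` object.
#' @param n_grid Number of grid points for the prediction line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mars_fit
#' @export
autoplot.mars_fit <- function(object, n_grid = 200, ...) {
  grid <- seq(min(object$data$age_weeks), max(object$data$age_weeks),
              length.out = n_grid)
  line <- tibble::tibble(age_weeks = grid,
                         weight_g = predict(object$model, grid))
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$age_weeks, y = .data$weight_g)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::labs(x = "Age (weeks)", y = "Body weight (g)",
                  title = "MARS fit") +
    ggplot2::theme_minimal()
  if (nrow(object$model$terms)) {
    p <- p + ggplot2::geom_vline(xintercept = unique(object$model$terms$knot),
                                 linetype = "dashed", alpha = 0.4)
  }
  p
}

#' Curve-overlay plot for a model comparison
#'
#' Observed per-age mean weights as points, with one predicted trajectory per
#' fitted model.
#'
#' @param object A `growth_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_comparison
#' @export
autoplot.growth_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$predictions,
                              cols = -c("age_weeks", "observed"),
                              names_to = "model", values_to = "predicted")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_weeks)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted, colour = .data$model)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 2) +
    ggplot2::labs(x = "Age (weeks)", y = "Body weight (g)", colour = "Model",
                  title = "Observed means and fitted growth curves") +
    ggplot2::theme_minimal()
}
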