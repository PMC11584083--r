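#' Read age-weight records from CSV
#'
#' Reads the package's CSV dialect: a header row, comma separation, `.`
#' decimal separator, UTF-8; columns `age_weeks` and `weight_g`, plus an
#' optional `id` column for per-bird records.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns (`id`,) `age_weeks`, `weight_g`.
#' @export
read_growth_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      stop("failed to parse '", path, "': ", conditionMessage(e), call. = FALSE)
    })
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop(sprintf("failed to parse '%s': problem at line %d (%s)", path,
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  need <- c("age_weeks", "weight_g")
  if (!all(need %in% names(raw)) || nrow(raw) == 0) {
    stop("'", path, "' must contain at least one record with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c("id", need), names(raw))
  out <- raw[keep]
  .validate_growth_data(out, for_fitting = FALSE)
  out
}

#' Write age-weight records to CSV
#'
#' @param data Data frame with `age_weeks` and `weight_g` (and optionally `id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(data, path) {
  .validate_growth_data(data, for_fitting = FALSE)
  readr::write_csv(data, path)
  invisible(path)
}

#' Serialize a model to JSON
#'
#' [growth_params()] objects round-trip as
#' `{"kind":"growth_model","family":...,"parameters":{...}}` and
#' [mars_model()] objects as
#' `{"kind":"mars_model","intercept":...,"terms":[...],"gcv":...}`.
#'
#' @param model A `growth_params` or `mars_model` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- if (inherits(model, "growth_params")) {
    list(kind = "growth_model", family = model$family,
         parameters = as.list(model$params))
  } else if (inherits(model, "mars_model")) {
    list(kind = "mars_model", intercept = model$intercept,
         terms = model$terms, gcv = model$gcv)
  } else {
    stop("`model` must be a growth_params or mars_model object", call. = FALSE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model from JSON
#'
#' Accepts documents written by [write_model_json()]; the model kind is
#' detected from the `kind` field, or from the presence of `family` versus
#' `intercept` fields when `kind` is absent.
#'
#' @param path Path to a model JSON file.
#' @return A `growth_params` or `mars_model` object.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- doc$kind %||%
    (if (!is.null(doc$family)) "growth_model"
     else if (!is.null(doc$intercept)) "mars_model"
     else stop("unknown model kind in '", path, "'", call. = FALSE))
  switch(kind,
    growth_model = do.call(growth_params,
                           c(list(family = doc$family), as.list(doc$parameters))),
    mars_model = {
      terms <- doc$terms
      if (is.null(terms) || (is.data.frame(terms) && nrow(terms) == 0)) terms <- NULL
      mars_model(intercept = doc$intercept, terms = terms, gcv = doc$gcv)
    },
    stop("unknown model kind '", kind, "' in '", path, "'", call. = FALSE)
  )
}

#' Read / write a simulation scenario
#'
#' Scenarios round-trip through JSON as a flat object with fields `family`,
#' `params` and the [simulate_flock()] options.
#'
#' @param path Path to a scenario JSON file.
#' @return `read_scenario_json()`: a named list suitable for
#'   [simulate_scenario()].
#' @export
read_scenario_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_scenario_json
#' @param scenario A named list describing the scenario.
#' @export
write_scenario_json <- function(scenario, path) {
  jsonlite::write_json(scenario, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
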