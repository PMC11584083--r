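#' Simulate weekly weighings of a broiler flock
#'
#' Generates longitudinal age-weight records with the statistical structure a
#' growth-curve analysis assumes: a smooth sigmoidal mean trajectory, per-bird
#' heterogeneity in mature size, and heteroscedastic measurement noise.
#' Bird `i` gets its own asymptote \eqn{A_i = A (1 + c_A z_i)} with
#' \eqn{z_i \sim N(0,1)}, and each weighing is perturbed multiplicatively,
#' \eqn{w = Y(t; A_i) (1 + c_e \epsilon)}, truncated below at 1 g so that no
#' record is non-positive. Body weights span two orders of magnitude between
#' hatch and slaughter, which is why constant-CV (multiplicative) error is the
#' default; an additive constant-SD option is available for textbook
#' homoscedastic recovery experiments.
#'
#' Defaults mirror a commercial fattening trial: 192 birds weighed weekly from
#' hatch to week 6, 8% between-bird CV in mature size, 5% measurement CV.
#'
#' @param params A [growth_params()] object giving the flock-mean trajectory.
#' @param n_birds Number of birds (>= 1).
#' @param ages Sorted non-negative vector of weighing ages (weeks).
#' @param asymptote_cv Relative SD of the per-bird asymptote (>= 0).
#' @param noise_cv Relative SD of multiplicative measurement error (>= 0).
#' @param seed Integer seed; identical scenario and seed reproduce the dataset
#'   bit-for-bit, and the caller's RNG state is left untouched.
#' @param noise `"multiplicative"` (default) or `"additive"`.
#' @param noise_sd Measurement SD in grams, used only for additive noise.
#' @return A tibble with columns `id`, `age_weeks`, `weight_g`.
#' @examples
#' p <- growth_params("gompertz", A = 6854.354, b = 4.882, k = 0.241)
#' simulate_flock(p, n_birds = 5, seed = 42)
#' @export
simulate_flock <- function(params, n_birds = 192, ages = 0:6,
                           asymptote_cv = 0.08, noise_cv = 0.05, seed = 1L,
                           noise = c("multiplicative", "additive"),
                           noise_sd = 20) {
  stopifnot(inherits(params, "growth_params"))
  noise <- match.arg(noise)
  n_birds <- as.integer(n_birds)
  ages <- as.numeric(ages)
  if (n_birds < 1) stop("`n_birds` must be >= 1", call. = FALSE)
  if (asymptote_cv < 0 || noise_cv < 0) {
    stop("`asymptote_cv` and `noise_cv` must be >= 0", call. = FALSE)
  }
  if (length(ages) == 0 || any(ages < 0) || is.unsorted(ages)) {
    stop("`ages` must be a sorted vector of non-negative weeks", call. = FALSE)
  }
  A <- params$params[["A"]]
  withr::with_seed(as.integer(seed), {
    Ai <- pmax(A * (1 + asymptote_cv * stats::rnorm(n_birds)), 1e-6)
    eps <- matrix(stats::rnorm(n_birds * length(ages)), nrow = n_birds)
  })
  rows <- lapply(seq_len(n_birds), function(i) {
    pi <- params
    pi$params[["A"]] <- Ai[i]
    mu <- .eval_family(pi$family, pi$params, ages)
    w <- if (noise == "multiplicative") mu * (1 + noise_cv * eps[i, ]) else
      mu + noise_sd * eps[i, ]
    tibble::tibble(id = i, age_weeks = ages, weight_g = pmax(w, 1))
  })
  dplyr::bind_rows(rows)
}

#' Simulate from a scenario description
#'
#' Convenience wrapper around [simulate_flock()] taking a plain list (e.g.
#' parsed from a JSON scenario file, see [read_scenario_json()]) with fields
#' `family`, `params` (named list), and optionally `n_birds`, `ages`,
#' `asymptote_cv`, `noise_cv`, `seed`, `noise`, `noise_sd`.
#'
#' @param scenario A named list.
#' @return A tibble as from [simulate_flock()].
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(is.list(scenario), !is.null(scenario$family), !is.null(scenario$params))
  params <- do.call(growth_params, c(list(family = scenario$family),
                                     as.list(scenario$params)))
  args <- scenario[intersect(names(scenario),
                             c("n_birds", "ages", "asymptote_cv", "noise_cv",
                               "seed", "noise", "noise_sd"))]
  do.call(simulate_flock, c(list(params = params), args))
}

#' Example dataset: weekly mean body weights of a male broiler flock
#'
#' Mean live weights (g) of male broiler chickens (Ross PM3) weighed weekly
#' from hatch to the sixth week of a commercial-style fattening period. These
#' seven flock means are the package's worked-example dataset; the same values
#' ship as a CSV fixture in `inst/extdata/broiler_weekly_weights.csv`.
#'
#' @return A tibble with columns `age_weeks` (0-6) and `weight_g`.
#' @examples
#' broiler_weekly_weights()
#' @export
broiler_weekly_weights <- function() {
  tibble::tibble(
    age_weeks = 0:6,
    weight_g = c(47.68, 151.76, 352.37, 613.21, 1033.27, 1607.70, 2193.10)
  )
}

#' Example growth-model parameters for the broiler dataset
#'
#' Parameter sets for all five families, estimated on the flock whose weekly
#' means [broiler_weekly_weights()] returns (fit on the underlying per-bird
#' records, which are not distributed). Useful as evaluation inputs: curves,
#' inflection points and prediction tables can be computed from them directly.
#'
#' @return A named list of [growth_params()] objects, one per family.
#' @examples
#' ref <- broiler_reference_parameters()
#' inflection(ref$gompertz)
#' @export
broiler_reference_parameters <- function() {
  path <- system.file("extdata", "broiler_reference_parameters.csv",
                      package = "flockfit", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  fams <- unique(tab$family)
  out <- lapply(fams, function(f) {
    rows <- tab[tab$family == f, ]
    do.call(growth_params,
            c(list(family = f), stats::setNames(as.list(rows$value), rows$parameter)))
  })
  stats::setNames(out, fams)
}
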