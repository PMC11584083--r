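# Seeded random parameter draws inside each family's valid domain, used by
# the property-style tests.
random_params <- function(family, seed) {
  withr::with_seed(seed, {
    A <- stats::runif(1, 1000, 12000)
    switch(family,
      logistic = growth_params("logistic", A = A,
                               b = stats::runif(1, 2, 60),
                               k = stats::runif(1, 0.1, 1.5)),
      gompertz = growth_params("gompertz", A = A,
                               b = stats::runif(1, 1.5, 8),
                               k = stats::runif(1, 0.1, 1)),
      weibull = growth_params("weibull", A = A,
                              b = A * stats::runif(1, 0.8, 0.999),
                              k = stats::runif(1, 0.003, 0.3),
                              lambda = stats::runif(1, 1.2, 3)),
      hossfeld = growth_params("hossfeld", A = A,
                               b1 = stats::runif(1, 5, 200),
                               b2 = stats::runif(1, 1.2, 3)),
      von_bertalanffy = growth_params("von_bertalanffy", A = A,
                                      b = stats::runif(1, 0.4, 0.95),
                                      k = stats::runif(1, 0.05, 0.5))
    )
  })
}

all_families <- function() growth_families()$family

# Central-difference second derivative of the growth curve in age.
num_d2 <- function(params, t, h = 1e-4) {
  (growth_curve(params, t + h) - 2 * growth_curve(params, t) +
     growth_curve(params, t - h)) / h^2
}
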