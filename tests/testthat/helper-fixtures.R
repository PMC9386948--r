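# Shared fixtures: small synthetic tables and fast sampler settings.

quick_iters <- 800L

# A small Model-1 synthetic table (K = 0).
quick_table <- function(seed = 42, nights = 80, beta1 = 1.2, tau = 2) {
  simulate_dataset(sim_config(n_nights = nights, beta1 = beta1, tau = tau,
                              seed = seed))
}

# A small table with two other-taxa groups (supports Models 3-4).
quick_table_k2 <- function(seed = 42, nights = 80) {
  simulate_dataset(sim_config(n_nights = nights, beta1 = 1.2, tau = 2,
                              other_taxa_means = c(15, 8), seed = seed))
}

quick_fit <- function(table, model = 1, seed = 7, iterations = quick_iters,
                      chains = 2) {
  suppressMessages(hlc_calibrate(table, model = model, iterations = iterations,
                                 chains = chains, seed = seed))
}

# Numerical quadrature of the Gamma-Poisson mixture pmf (independent oracle).
# The integrand dpois(N; theta*lambda) * dgamma(theta; tau*lambda, tau*lambda)
# is proportional to a Gamma(N + tau*lambda, lambda + tau*lambda) kernel in
# theta, so quadrature over that envelope's extreme quantiles loses no mass.
mixture_pmf_quad <- function(N, lambda, tau) {
  if (lambda == 0) return(as.numeric(N == 0))
  sh <- N + tau * lambda
  rt <- lambda + tau * lambda
  lower <- stats::qgamma(1e-16, shape = sh, rate = rt)
  upper <- stats::qgamma(1e-16, shape = sh, rate = rt, lower.tail = FALSE)
  stats::integrate(function(theta) {
    stats::dpois(N, theta * lambda) *
      stats::dgamma(theta, shape = tau * lambda, rate = tau * lambda)
  }, lower = lower, upper = upper, rel.tol = 1e-12)$value
}

# Records covering one night, two traps, three taxa (worked example rows).
one_night_records <- function() {
  df <- data.frame(
    date = as.Date("2015-04-01"), village = "Lupiro",
    trap = c("HLC", "SUN", "SUN", "SUN"),
    taxon = c("an_arabiensis", "an_arabiensis", "culex", "an_funestus"),
    hour = NA_integer_, count = c(7L, 4L, 10L, 1L),
    stringsAsFactors = FALSE)
  class(df) <- c("catch_records", "data.frame")
  df
}
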