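test_that("build_lambda implements the origin-constrained power law", {
  tab <- catch_table(N = c(0L, 0L), n = c(10L, 0L))
  spec <- model_spec(1)
  lam <- build_lambda(spec, c(beta1 = 2, tau = 1), tab)
  expect_equal(lam, c(100, 0)) # 10^2, and the origin at n = 0
  # raw scale applies the linear predictor literally
  lam_raw <- build_lambda(model_spec(1, "raw"), c(beta1 = 0.1, tau = 1), tab)
  expect_equal(lam_raw[1], exp(1))
})

test_that("build_lambda covers the density-dependent model structures", {
  tab <- catch_table(N = 0L, n = 5L, s = matrix(c(3L, 7L), 1, 2))
  ln <- log(5)
  expect_equal(
    build_lambda(model_spec(2, K = 2), c(beta1 = 1, beta2 = 0.1, tau = 1), tab),
    exp(ln + 0.1 * ln^2))
  expect_equal(
    build_lambda(model_spec(3, K = 2), c(beta1 = 1, beta2 = 0.1, tau = 1), tab),
    exp(ln + 0.1 * ln * log1p(10)))
  expect_equal(
    build_lambda(model_spec(4, K = 2),
                 list(beta1 = 1, beta_k = c(0.1, 0.2), tau = 1), tab),
    exp(ln + 0.1 * ln * log1p(3) + 0.2 * ln * log1p(7)))
  tab0 <- catch_table(N = 0L, n = 5L)
  expect_error(model_spec(3, K = tab0$K), "K >= 1")
  expect_error(model_spec(4, K = 0), "K >= 1")
})

test_that("lambda is monotone in n under positive parameters (log scale)", {
  n_grid <- 0:60
  set.seed(1)
  for (rep in 1:20) {
    spec <- model_spec(sample(1:2, 1))
    params <- c(beta1 = rexp(1) + 0.05, beta2 = rexp(1, 10) + 0.01, tau = 1)
    tab <- catch_table(N = integer(length(n_grid)), n = n_grid)
    lam <- build_lambda(spec, params, tab)
    expect_true(all(diff(lam) >= 0))
  }
})

test_that("negbin_logpmf has the Gamma-Poisson closed form", {
  expect_equal(negbin_logpmf(0, 1, 1), log(0.5))
  expect_equal(negbin_logpmf(0, 0, 3), 0)
  expect_identical(negbin_logpmf(2, 0, 3), -Inf)
  expect_error(negbin_logpmf(1.5, 1, 1), "non-negative integer")
  expect_error(negbin_logpmf(1, 1, -1), "tau must be positive")
  # quadrature oracle at the spec'd worked example
  expect_equal(exp(negbin_logpmf(4, 2, 3)), mixture_pmf_quad(4, 2, 3),
               tolerance = 1e-8)
})

test_that("negbin_logpmf matches its stated mean and variance", {
  for (case in list(c(2, 0.5), c(5, 2), c(20, 3))) {
    lambda <- case[1]; tau <- case[2]
    N <- 0:2000
    p <- exp(negbin_logpmf(N, lambda, tau))
    expect_equal(sum(p * N), lambda, tolerance = 1e-6)
    expect_equal(sum(p * N^2) - lambda^2, lambda * (1 + 1 / tau),
                 tolerance = 1e-5)
  }
})

test_that("log_prior is the sum of gamma log-densities on the positive orthant", {
  pr <- prior_spec()
  lp1 <- log_prior(c(beta1 = 1, tau = 1), pr)
  closed <- (0.1 * log(0.1) - lgamma(0.1) - 0.1) +
    (0.01 * log(0.01) - lgamma(0.01) - 0.01)
  expect_equal(lp1, closed)
  expect_identical(log_prior(c(beta1 = 0, tau = 1), pr), -Inf)
  # additivity: duplicating an identical slope doubles its contribution
  beta_part <- log_prior(c(beta1 = 2, tau = 1), pr) -
    dgamma(1, 0.01, rate = 0.01, log = TRUE)
  two_part <- log_prior(c(beta1 = 2, beta2 = 2, tau = 1), pr) -
    dgamma(1, 0.01, rate = 0.01, log = TRUE)
  expect_equal(two_part, 2 * beta_part)
})

test_that("log_posterior decomposes into per-night likelihood plus prior", {
  spec <- model_spec(1)
  pr <- prior_spec()
  params <- c(beta1 = 1.1, tau = 2)
  empty <- catch_table(N = integer(0), n = integer(0))
  expect_equal(log_posterior(params, spec, empty, pr), log_prior(params, pr))

  tab <- quick_table(seed = 3, nights = 25)
  lam <- build_lambda(spec, params, tab)
  keep <- tab$n > 0
  by_night <- sum(negbin_logpmf(tab$N[keep], lam[keep], params[["tau"]]))
  expect_equal(log_posterior(params, spec, tab, pr),
               by_night + log_prior(params, pr))

  single <- tab[which(keep)[1]]
  expect_equal(log_posterior(params, spec, single, pr),
               negbin_logpmf(single$N, build_lambda(spec, params, single),
                             params[["tau"]]) + log_prior(params, pr))
})

test_that("log_posterior is invariant to night order", {
  tab <- quick_table(seed = 9, nights = 40)
  perm <- tab[sample(seq_along(tab$N))]
  params <- c(beta1 = 1.2, tau = 2)
  spec <- model_spec(1)
  expect_equal(log_posterior(params, spec, tab),
               log_posterior(params, spec, perm))
})

test_that("model configs round-trip through YAML and JSON", {
  spec <- model_spec(3, "log", K = 2)
  pr <- prior_spec(beta_shape = 0.2, beta_rate = 0.3)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model_config(path, spec, pr)
    cfg <- read_model_config(path)
    expect_equal(cfg$spec, spec)
    expect_equal(cfg$priors, pr)
  }
})
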