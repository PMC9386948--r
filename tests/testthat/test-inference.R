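test_that("identical seeds reproduce identical draws bit-for-bit", {
  tab <- quick_table(seed = 2, nights = 40)
  spec <- model_spec(1)
  d1 <- suppressMessages(sample_posterior(spec, tab, iterations = 400, seed = 5))
  d2 <- suppressMessages(sample_posterior(spec, tab, iterations = 400, seed = 5))
  expect_identical(d1$draws, d2$draws)
  d3 <- suppressMessages(sample_posterior(spec, tab, iterations = 400, seed = 6))
  expect_false(identical(d1$draws, d3$draws))
})

test_that("sampler validates its settings and draws stay positive", {
  tab <- quick_table(seed = 2, nights = 40)
  spec <- model_spec(1)
  expect_error(sample_posterior(spec, tab, iterations = 0), "iterations")
  dr <- suppressMessages(sample_posterior(spec, tab, iterations = 600, seed = 1))
  expect_true(all(dr$draws > 0))
  expect_equal(dr$param_names, c("beta1", "tau"))
  expect_true(all(dr$accept_rates > 0.01))
})

test_that("posterior mean recovers a known Model 1 truth", {
  tab <- simulate_dataset(sim_config(n_nights = 250, beta1 = 1.2, tau = 2,
                                     seed = 31))
  dr <- suppressMessages(sample_posterior(model_spec(1), tab,
                                          iterations = 4000, seed = 31))
  expect_lt(abs(mean(dr$draws[, "beta1"]) - 1.2), 0.1)
})

test_that("split R-hat is near 1 for matching chains and large for disjoint ones", {
  set.seed(99)
  x <- exp(rnorm(6000, 0, 0.1))
  same <- posterior_draws(cbind(beta1 = c(x, x)),
                          chain = rep(1:2, each = 6000))
  expect_lt(abs(rhat(same)[["beta1"]] - 1), 0.001)

  apart <- posterior_draws(cbind(beta1 = c(exp(rnorm(500, 0, 0.01)),
                                           exp(rnorm(500, 3, 0.01)))),
                           chain = rep(1:2, each = 500))
  expect_gt(rhat(apart)[["beta1"]], 1.1)

  one <- posterior_draws(cbind(beta1 = x), chain = rep(1L, length(x)))
  expect_error(rhat(one), "chains >= 2")
})

test_that("well-mixed chains on synthetic data converge (R-hat < 1.05)", {
  fit <- quick_fit(quick_table(seed = 8, nights = 100), iterations = 4000)
  expect_true(all(fit$rhat < 1.05))
})

test_that("DIC satisfies its internal identities on every fit", {
  for (mdl in c(1, 4)) {
    tab <- quick_table_k2(seed = 12, nights = 60)
    fit <- quick_fit(tab, model = mdl)
    d <- fit$dic
    expect_identical(d$dic, d$mean_deviance + d$p_d)
    expect_identical(d$p_d, d$mean_deviance - d$deviance_at_mean)
  }
})

test_that("a degenerate posterior has p_d = 0 and dic = deviance at the mean", {
  tab <- quick_table(seed = 4, nights = 30)
  point <- matrix(rep(c(1.2, 2), each = 10), ncol = 2,
                  dimnames = list(NULL, c("beta1", "tau")))
  dr <- posterior_draws(point)
  d <- compute_dic(dr, model_spec(1), tab)
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, d$deviance_at_mean)
})

test_that("DIC matches a brute-force two-draw hand computation", {
  tab <- catch_table(N = 6L, n = 4L)
  draws <- matrix(c(1.0, 1.5, 2.0, 1.0), ncol = 2,
                  dimnames = list(NULL, c("beta1", "tau")))
  dr <- posterior_draws(draws)
  dev <- function(beta1, tau) {
    -2 * negbin_logpmf(6L, 4^beta1, tau)
  }
  mean_dev <- mean(c(dev(1.0, 2.0), dev(1.5, 1.0)))
  dev_at_mean <- dev(1.25, 1.5)
  d <- compute_dic(dr, model_spec(1), tab)
  expect_equal(d$mean_deviance, mean_dev)
  expect_equal(d$deviance_at_mean, dev_at_mean)
  expect_equal(d$dic, 2 * mean_dev - dev_at_mean)
  expect_error(compute_dic(dr, model_spec(2), tab), "parameterization")
})

test_that("permuting night order leaves DIC and seeded draws unchanged", {
  tab <- quick_table(seed = 21, nights = 50)
  set.seed(1)
  perm <- tab[sample(seq_along(tab$N))]
  spec <- model_spec(1)
  d1 <- suppressMessages(sample_posterior(spec, tab, iterations = 400, seed = 9))
  d2 <- suppressMessages(sample_posterior(spec, perm, iterations = 400, seed = 9))
  expect_equal(d1$draws, d2$draws)
  expect_equal(compute_dic(d1, spec, tab)$dic, compute_dic(d2, spec, perm)$dic)
})
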