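point_draws <- function(beta1 = 1.1442, tau = 2, reps = 5) {
  posterior_draws(matrix(rep(c(beta1, tau), each = reps), ncol = 2,
                         dimnames = list(NULL, c("beta1", "tau"))))
}

test_that("a point-mass posterior predicts the plug-in curve with zero width", {
  pr <- predict_hlc(point_draws(), model_spec(1), n_new = c(0L, 100L))
  expect_equal(pr$mean[1], 0)
  expect_equal(pr$lo[1], 0)
  expect_equal(pr$hi[1], 0)
  expect_equal(pr$mean[2], 100^1.1442, tolerance = 1e-12)
  expect_equal(pr$lo[2], pr$mean[2])
  expect_equal(pr$hi[2], pr$mean[2])
  # the zero-intercept exponent fitted to the published SUN column
  expect_equal(round(pr$mean[2]), 194)
})

test_that("predictions are monotone in the collected count (Models 1-2)", {
  fit <- quick_fit(quick_table(seed = 10, nights = 80))
  pr <- predict(fit, n_new = c(1L, 5L, 20L, 50L, 100L))
  expect_true(all(diff(pr$mean) > 0))
  expect_true(all(pr$lo <= pr$mean & pr$mean <= pr$hi))
})

test_that("posterior-mean predictions dominate plug-in predictions (Jensen)", {
  fit <- quick_fit(quick_table(seed = 10, nights = 80))
  plug <- predict_hlc(point_draws(coef(fit)[["beta1"]], coef(fit)[["tau"]]),
                      fit$spec, n_new = c(2L, 10L, 100L))
  post <- predict(fit, n_new = c(2L, 10L, 100L))
  expect_true(all(post$mean >= plug$mean))
})

test_that("models with density dependence require reference covariates", {
  tab <- quick_table_k2(seed = 13, nights = 60)
  fit3 <- quick_fit(tab, model = 3)
  expect_error(predict_hlc(fit3$draws, fit3$spec, n_new = 10L),
               "require reference covariate.*m")
  fit4 <- quick_fit(tab, model = 4)
  expect_error(predict_hlc(fit4$draws, fit4$spec, n_new = 10L),
               "require reference covariate.*s")
  # the fit method fills in sample medians
  pr <- predict(fit3, n_new = c(10L, 20L))
  expect_true(all(pr$mean > 0))
  pr4 <- predict(fit4, n_new = c(10L, 20L))
  expect_true(all(pr4$mean > 0))
})

test_that("predictive intervals are wider than credible intervals", {
  fit <- quick_fit(quick_table(seed = 10, nights = 80))
  set.seed(1)
  cr <- predict(fit, n_new = 50L, interval = "credible")
  pd <- predict(fit, n_new = 50L, interval = "predictive")
  expect_gt(pd$hi - pd$lo, cr$hi - cr$lo)
})

test_that("lookup tables are rounded views of predict_hlc, row by row", {
  fit <- quick_fit(quick_table(seed = 10, nights = 80))
  grid <- seq(10L, 100L, by = 10L)
  lt <- make_lookup_table(fit, grid = grid)
  expect_equal(nrow(lt), 10L)
  expect_true(all(lt$lo95 <= lt$expected_hlc & lt$expected_hlc <= lt$hi95))
  pr <- predict_hlc(fit$draws, fit$spec, grid)
  expect_equal(lt$expected_hlc, as.integer(round(pr$mean)))
  expect_equal(lt$lo95, as.integer(round(pr$lo)))
  expect_equal(lt$hi95, as.integer(round(pr$hi)))
  un <- attr(lt, "unrounded")
  expect_equal(un$mean, pr$mean)
  expect_error(make_lookup_table(fit, grid = c(10L, 10L, 20L)),
               "strictly increasing")
  expect_error(make_lookup_table(fit, grid = integer(0)), "non-empty")
})

test_that("fit_published_curve reproduces exact power laws with zero residual", {
  pc1 <- fit_published_curve(c(10, 100), c(10, 100))
  expect_equal(pc1$beta1, 1)
  expect_equal(predict(pc1, 7), 7)

  n <- c(2, 4, 8, 16)
  pc2 <- fit_published_curve(n, n^1.5)
  expect_equal(pc2$beta1, 1.5)
  expect_equal(max(abs(pc2$residuals)), 0, tolerance = 1e-12)

  expect_error(fit_published_curve(c(1, -2), c(1, 2)), "strictly positive")
  expect_error(fit_published_curve(5, 5), "at least 2")
})

test_that("the published SUN conversion column is recovered at n = 100", {
  ref <- reference_conversions(taxon = "an_arabiensis", trap = "SUN")
  pc <- fit_published_curve(ref$collected[1:9], ref$hlc[1:9])
  expect_equal(round(predict(pc, 100)), 194)
})
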