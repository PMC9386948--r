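# Main fitting interface: hlc_calibrate() and the "hlc_fit" methods.

summarize_draws <- function(draws) {
  qs <- t(apply(draws$draws, 2, quantile, probs = c(0.025, 0.5, 0.975)))
  cbind(mean = colMeans(draws$draws),
        sd = apply(draws$draws, 2, sd),
        `2.5%` = qs[, 1], `50%` = qs[, 2], `97.5%` = qs[, 3])
}

# Posterior mean of lambda per night, averaged draw by draw (in blocks to
# bound memory).
posterior_mean_lambda <- function(draws, spec, table, block = 2000L) {
  lf <- make_lambda_fun(spec, table)
  B <- draws$draws
  acc <- numeric(length(table$N))
  nd <- nrow(B)
  i <- 1L
  while (i <= nd) {
    j <- min(i + block - 1L, nd)
    for (r in i:j) acc <- acc + lf(B[r, ])
    i <- j + 1L
  }
  acc / nd
}

#' Calibrate an alternative trap against the human landing catch
#'
#' Fits one of the four Gamma-Poisson mixture models (see [model_spec()]) to
#' an aligned catch table by MCMC ([sample_posterior()]), then computes the
#' DIC ([compute_dic()]), per-parameter posterior summaries, split-chain
#' R-hat, posterior-mean fitted values and the pseudo-R-squared.
#'
#' @param table A `"catch_table"` (see [build_catch_table()]).
#' @param model Integer 1--4 selecting the mean model.
#' @param scale `"log"` (origin-constrained power law, default) or `"raw"`.
#' @param priors A `"prior_spec"`.
#' @param iterations,chains,seed Sampler settings; see [sample_posterior()].
#' @return An object of class `"hlc_fit"` with components `spec`, `priors`,
#'   `table`, `draws`, `coefficients` (posterior means), `summary`, `rhat`,
#'   `dic`, `fitted`, `pseudo_r2` and `settings`.
#' @examples
#' cfg <- sim_config(n_nights = 60, beta1 = 1.2, tau = 2, seed = 7)
#' tab <- simulate_dataset(cfg)
#' fit <- hlc_calibrate(tab, model = 1, iterations = 800, seed = 7)
#' coef(fit)
#' @export
hlc_calibrate <- function(table, model = 1, scale = c("log", "raw"),
                          priors = prior_spec(), iterations = 30000,
                          chains = 2, seed = 1) {
  stopifnot(inherits(table, "catch_table"))
  scale <- match.arg(scale)
  spec <- model_spec(model, scale, K = table$K)
  draws <- sample_posterior(spec, table, priors, iterations = iterations,
                            chains = chains, seed = seed)
  dic <- compute_dic(draws, spec, table)
  sm <- summarize_draws(draws)
  rh <- if (chains >= 2) rhat(draws) else NULL
  fit_lambda <- posterior_mean_lambda(draws, spec, table)
  r2 <- pseudo_r2(table$N, fit_lambda)
  n_zero <- if (scale == "log") sum(table$n == 0) else 0L
  structure(list(call = match.call(), spec = spec, priors = priors,
                 table = table, draws = draws,
                 coefficients = setNames(sm[, "mean"], rownames(sm)),
                 summary = sm, rhat = rh, dic = dic, fitted = fit_lambda,
                 pseudo_r2 = r2, n_zero_dropped = n_zero,
                 settings = list(iterations = iterations, chains = chains,
                                 seed = seed)),
            class = "hlc_fit")
}

#' @export
print.hlc_fit <- function(x, digits = 3, ...) {
  cat("Trap-to-HLC calibration fit",
      if (!is.na(x$table$trap)) paste0("(", x$table$trap, " vs HLC",
        if (!is.na(x$table$taxon)) paste0(", ", x$table$taxon), ")"), "\n")
  cat("  ", model_structure(x$spec), "\n", sep = "")
  cat("  nights:", length(x$table$N),
      if (x$n_zero_dropped > 0) paste0("(", x$n_zero_dropped,
                                       " zero-catch nights excluded)"), "\n")
  cat("Posterior means:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("DIC %.1f (pD %.1f)  pseudo-R2 %.1f%%\n",
              x$dic$dic, x$dic$p_d, x$pseudo_r2))
  invisible(x)
}

#' @export
coef.hlc_fit <- function(object, ...) object$coefficients

#' @export
fitted.hlc_fit <- function(object, ...) object$fitted

#' Residuals of a calibration fit
#'
#' @param object An `"hlc_fit"`.
#' @param type `"response"` (`N - lambda_hat`) or `"pearson"` (standardised
#'   by the negative binomial standard deviation
#'   `sqrt(lambda * (1 + 1/tau))` at the posterior means).
#' @param ... Unused.
#' @return Numeric vector, one residual per night.
#' @export
residuals.hlc_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$table$N - object$fitted
  if (type == "pearson") {
    tau <- object$coefficients[["tau"]]
    sdv <- sqrt(object$fitted * (1 + 1 / tau))
    r <- ifelse(sdv > 0, r / sdv, 0)
  }
  r
}

#' @export
summary.hlc_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.hlc_fit")
}

#' @export
print.summary.hlc_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  tab <- f$summary
  if (!is.null(f$rhat)) tab <- cbind(tab, Rhat = f$rhat)
  cat("\nPosterior summary:\n")
  print(round(tab, digits))
  cat(sprintf("\nSampler: %d iterations x %d chain(s), seed %s; acceptance %s\n",
              f$settings$iterations, f$settings$chains,
              format(f$settings$seed),
              paste(sprintf("%.2f", f$draws$accept_rates), collapse = "/")))
  invisible(x)
}

#' Predict HLC-equivalents from a fitted calibration
#'
#' @param object An `"hlc_fit"`.
#' @param n_new Non-negative integer trap counts to convert.
#' @param m,s Reference values for the other-taxa covariates (Models 3--4);
#'   default to the per-night medians of the fitted table.
#' @param interval `"credible"` (interval on the expected catch `lambda`,
#'   default) or `"predictive"` (interval on a new night's count).
#' @param level Interval coverage (default 0.95).
#' @param ... Unused.
#' @return A data frame with columns `n`, `mean`, `lo`, `hi`.
#' @export
predict.hlc_fit <- function(object, n_new, m = NULL, s = NULL,
                            interval = c("credible", "predictive"),
                            level = 0.95, ...) {
  interval <- match.arg(interval)
  if (object$spec$model >= 3) {
    if (object$spec$model == 3 && is.null(m)) m <- median(object$table$m)
    if (object$spec$model == 4 && is.null(s)) {
      s <- apply(object$table$s, 2, median)
    }
  }
  predict_hlc(object$draws, object$spec, n_new, m = m, s = s,
              interval = interval, level = level)
}

#' Simulate posterior-predictive nightly HLC counts
#'
#' For each simulation one posterior draw is selected at random; nightly
#' means `lambda_i` are computed for the fitted table and a count is drawn
#' from the Gamma-Poisson mixture.
#'
#' @param object An `"hlc_fit"`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed, handled as in [stats::simulate()].
#' @param ... Unused.
#' @return A data frame (nights x nsim) of simulated counts.
#' @export
simulate.hlc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lf <- make_lambda_fun(object$spec, object$table)
  B <- object$draws$draws
  nights <- length(object$table$N)
  out <- matrix(NA_integer_, nrow = nights, ncol = nsim)
  for (k in seq_len(nsim)) {
    th <- B[sample.int(nrow(B), 1L), ]
    lam <- lf(th)
    tau <- th[["tau"]]
    N <- integer(nights)
    pos <- lam > 0
    N[pos] <- rnbinom(sum(pos), size = tau * lam[pos], prob = tau / (tau + 1))
    out[, k] <- N
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a calibration fit
#'
#' Scatter of nightly (trap count, HLC count) pairs with the posterior-mean
#' prediction curve and credible band overlaid.
#'
#' @param x An `"hlc_fit"`.
#' @param grid Trap counts at which to evaluate the curve; defaults to an
#'   even grid from 0 to the maximum observed trap count.
#' @param level Credible level for the band.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.hlc_fit <- function(x, grid = NULL, level = 0.95, ...) {
  tab <- x$table
  if (is.null(grid)) grid <- unique(round(seq(0, max(tab$n, 1), length.out = 50)))
  pr <- predict(x, n_new = grid, level = level)
  ylim <- range(0, tab$N, pr$hi, finite = TRUE)
  plot(tab$n, tab$N, pch = 16, col = "grey40",
       xlab = paste0("collected (", if (is.na(tab$trap)) "trap" else tab$trap, ")"),
       ylab = "HLC count", ylim = ylim, ...)
  lines(pr$n, pr$mean, lwd = 2)
  lines(pr$n, pr$lo, lty = 2)
  lines(pr$n, pr$hi, lty = 2)
  legend("topleft", bty = "n",
         legend = c("observed nights", "posterior mean",
                    sprintf("%d%% credible band", round(level * 100))),
         pch = c(16, NA, NA), lty = c(NA, 1, 2), lwd = c(NA, 2, 1),
         col = c("grey40", "black", "black"))
  invisible(x)
}
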