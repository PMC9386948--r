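# Synthetic trap-night data with the generative structure the models assume.

#' Configuration for the synthetic trap-night generator
#'
#' The generator emulates a season of paired trap-nights: the focal
#' alternative-trap count `n` (and each other-taxa count `s_k`) is drawn
#' from an overdispersed negative binomial marginal, and the HLC response
#' is drawn from the Gamma-Poisson mixture at the model-implied mean
#' `lambda`. Defaults mirror a desk-scale field season: 250 trap-nights,
#' a mean nightly catch of 20 with strong overdispersion, and a mildly
#' superlinear Model 1 truth (`beta1 = 1.2`, `tau = 2`).
#'
#' @param n_nights Number of nights (>= 1).
#' @param mean_catch Mean of the focal-trap counts `n`.
#' @param catch_dispersion Negative binomial size parameter of the covariate
#'   marginals (smaller = more overdispersed).
#' @param model,scale Mean-model choice; see [model_spec()].
#' @param beta1,beta2,beta_k,tau True parameter values (`beta2` for Models
#'   2--3, `beta_k` a length-K vector for Model 4).
#' @param other_taxa_means Mean nightly counts of the K other-taxa groups
#'   (empty for none, giving `m = 0`).
#' @param seed Integer seed.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_nights = 250L, mean_catch = 20, catch_dispersion = 1,
                       model = 1L, scale = c("log", "raw"), beta1 = 1.2,
                       beta2 = NULL, beta_k = NULL, tau = 2,
                       other_taxa_means = numeric(0), seed = 1L) {
  scale <- match.arg(scale)
  n_nights <- as.integer(n_nights)
  if (n_nights < 1) stop("n_nights must be >= 1")
  if (mean_catch <= 0 || catch_dispersion <= 0) {
    stop("mean_catch and catch_dispersion must be positive")
  }
  if (length(other_taxa_means) > 0 && any(other_taxa_means <= 0)) {
    stop("other_taxa_means must be positive")
  }
  K <- length(other_taxa_means)
  spec <- model_spec(model, scale, K = K)
  params <- list(beta1 = beta1, tau = tau)
  if (spec$model %in% c(2L, 3L)) {
    if (is.null(beta2)) stop("Model ", spec$model, " requires beta2")
    params$beta2 <- beta2
  }
  if (spec$model == 4L) {
    if (is.null(beta_k) || length(beta_k) != K) {
      stop("Model 4 requires beta_k with one entry per other-taxa group")
    }
    params$beta_k <- beta_k
  }
  true <- as_model_params(spec, params)
  if (anyNA(true) || any(true <= 0)) stop("all true parameters must be positive")
  structure(list(n_nights = n_nights, mean_catch = mean_catch,
                 catch_dispersion = catch_dispersion, spec = spec,
                 true_params = true, other_taxa_means = other_taxa_means,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trap-night configuration:", x$n_nights, "nights, Model",
      x$spec$model, "(", x$spec$scale, "scale ), seed", x$seed, "\n")
  cat("  covariates: mean", x$mean_catch, ", dispersion", x$catch_dispersion,
      ",", length(x$other_taxa_means), "other-taxa group(s)\n")
  cat("  truth:", paste(sprintf("%s=%g", names(x$true_params), x$true_params),
                        collapse = ", "), "\n")
  invisible(x)
}

# Covariate draws without touching the seed (callers seed first).
draw_covariates <- function(config) {
  nn <- config$n_nights
  n <- rnbinom(nn, mu = config$mean_catch, size = config$catch_dispersion)
  K <- length(config$other_taxa_means)
  s <- if (K > 0) {
    vapply(config$other_taxa_means,
           function(mu) rnbinom(nn, mu = mu, size = config$catch_dispersion),
           numeric(nn))
  } else matrix(integer(), nrow = nn, ncol = 0)
  s <- matrix(as.integer(s), nrow = nn)
  if (K > 0) colnames(s) <- paste0("taxon_", seq_len(K))
  list(n = as.integer(n), s = s, m = as.integer(rowSums(s)))
}

#' Simulate per-night trap covariates
#'
#' Draws the focal-trap counts `n` and each other-taxa count `s_k`
#' independently from negative binomial marginals with the configured means
#' and dispersion; `m` is the per-night sum of the `s_k`. Seeded and
#' reproducible.
#'
#' @param config A `"sim_config"`.
#' @return A list with elements `n` (integer vector), `m` (integer vector)
#'   and `s` (integer matrix, nights x K).
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  draw_covariates(config)
}

#' Simulate a full synthetic catch table
#'
#' Given simulated covariates, the nightly mean is
#' `lambda = build_lambda(true_params)`; the HLC count is then drawn from
#' the Gamma-Poisson mixture, `theta ~ Gamma(tau * lambda, tau * lambda)`
#' and `N ~ Poisson(theta * lambda)`. Nights with `lambda = 0` get `N = 0`
#' (the origin assumption). The same seed reproduces the same dataset.
#'
#' @param config A `"sim_config"`.
#' @return A `"catch_table"` carrying the simulated nights.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cov <- draw_covariates(config)
  tab <- catch_table(N = integer(config$n_nights), n = cov$n,
                     s = if (ncol(cov$s) > 0) cov$s else NULL,
                     taxon = "synthetic", trap = NA_character_)
  lam <- build_lambda(config$spec, config$true_params, tab)
  tau <- config$true_params[["tau"]]
  N <- integer(config$n_nights)
  pos <- lam > 0
  if (any(pos)) {
    theta <- rgamma(sum(pos), shape = tau * lam[pos], rate = tau * lam[pos])
    N[pos] <- rpois(sum(pos), theta * lam[pos])
  }
  tab$N <- N
  tab
}

#' Flatten a catch table into standard long-format records
#'
#' Emits one record per (night, trap, taxon) in the catch CSV schema, so a
#' simulated table can flow through the identical pipeline as real data
#' ([write_catch_csv()] then [read_catch_csv()], [pool_hourly()],
#' [build_catch_table()]).
#'
#' @param table A `"catch_table"`.
#' @param trap Trap code for the alternative-trap rows (default `"SUN"`).
#' @param taxon Focal taxon label (default `"an_arabiensis"`).
#' @param village Village label.
#' @param start_date Date of the first night; nights are consecutive.
#' @return A `"catch_records"` data frame.
#' @export
as_catch_records <- function(table, trap = "SUN", taxon = "an_arabiensis",
                             village = "SimVillage",
                             start_date = as.Date("2015-04-01")) {
  stopifnot(inherits(table, "catch_table"))
  trap <- normalize_trap(trap)
  nights <- length(table$N)
  dates <- start_date + seq_len(nights) - 1L
  rows <- list(
    data.frame(date = dates, village = village, trap = "HLC", taxon = taxon,
               hour = NA_integer_, count = table$N, stringsAsFactors = FALSE),
    data.frame(date = dates, village = village, trap = trap, taxon = taxon,
               hour = NA_integer_, count = table$n, stringsAsFactors = FALSE))
  if (table$K > 0) {
    for (k in seq_len(table$K)) {
      rows[[length(rows) + 1L]] <-
        data.frame(date = dates, village = village, trap = trap,
                   taxon = table$other_taxa[k], hour = NA_integer_,
                   count = table$s[, k], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$date, out$trap, out$taxon), ]
  rownames(out) <- NULL
  class(out) <- c("catch_records", "data.frame")
  out
}

#' Simulate-fit-check parameter recovery experiment
#'
#' For each replicate: simulate a dataset under the configured truth, fit
#' the same model by MCMC, and record whether each true parameter falls in
#' its 95% equal-tailed credible interval along with the point-estimate
#' error. Replicate `r` uses seed `config$seed + r` for both simulation and
#' fitting, so the whole experiment is reproducible.
#'
#' @param config A `"sim_config"`.
#' @param replicates Number of replicates (>= 1).
#' @param iterations,chains Sampler settings per replicate fit.
#' @param priors A `"prior_spec"`.
#' @return An object of class `"recovery_experiment"`: per-replicate results
#'   plus `coverage` (empirical 95%-interval coverage per parameter) and
#'   `bias` (mean posterior-mean error per parameter).
#' @export
recovery_experiment <- function(config, replicates = 50L, iterations = 30000L,
                                chains = 2L, priors = prior_spec()) {
  stopifnot(inherits(config, "sim_config"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1) stop("replicates must be >= 1")
  truth <- config$true_params
  pn <- names(truth)
  res <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    tab <- simulate_dataset(cfg)
    dr <- suppressMessages(
      sample_posterior(config$spec, tab, priors, iterations = iterations,
                       chains = chains, seed = cfg$seed))
    est <- colMeans(dr$draws)
    lo <- apply(dr$draws, 2, quantile, probs = 0.025)
    hi <- apply(dr$draws, 2, quantile, probs = 0.975)
    res[[r]] <- data.frame(replicate = r, param = pn, truth = unname(truth),
                           estimate = unname(est[pn]), lo95 = unname(lo[pn]),
                           hi95 = unname(hi[pn]),
                           covered = unname(lo[pn] <= truth & truth <= hi[pn]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  coverage <- tapply(res$covered, res$param, mean)[pn]
  bias <- tapply(res$estimate - res$truth, res$param, mean)[pn]
  structure(list(results = res, coverage = coverage, bias = bias,
                 truth = truth,
                 settings = list(replicates = replicates,
                                 iterations = iterations, chains = chains,
                                 seed = config$seed)),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("Parameter recovery over", x$settings$replicates, "replicates\n")
  print(data.frame(truth = x$truth,
                   coverage = round(as.numeric(x$coverage), 3),
                   mean_bias = round(as.numeric(x$bias), 4)))
  invisible(x)
}
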