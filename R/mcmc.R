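# Posterior sampling, convergence diagnostics and DIC.

#' Container for MCMC draws
#'
#' Holds posterior draws on the natural (positive) scale together with chain
#' labels and sampler metadata. Normally produced by [sample_posterior()];
#' the constructor is exported so diagnostic utilities can be applied to
#' externally assembled draws.
#'
#' @param draws Numeric matrix (iterations x parameters) with column names;
#'   all entries must be strictly positive.
#' @param chain Integer vector of chain labels, one per row.
#' @param n_chains Number of chains.
#' @param seed RNG seed the draws were generated under.
#' @param accept_rates Named per-parameter post-burn-in acceptance fractions.
#' @param iterations,burn Total iterations per chain and burn-in length.
#' @return An object of class `"posterior_draws"`.
#' @export
posterior_draws <- function(draws, chain = NULL, n_chains = NULL, seed = NA,
                            accept_rates = NULL, iterations = NA, burn = NA) {
  draws <- as.matrix(draws)
  if (is.null(colnames(draws))) stop("draws must have parameter column names")
  if (nrow(draws) == 0) stop("draws must contain at least one iteration")
  if (anyNA(draws) || any(draws <= 0)) {
    stop("all draws must be strictly positive (natural scale)")
  }
  if (is.null(chain)) chain <- rep(1L, nrow(draws))
  if (length(chain) != nrow(draws)) stop("chain labels must match rows of draws")
  if (is.null(n_chains)) n_chains <- length(unique(chain))
  structure(list(draws = draws, chain = as.integer(chain),
                 n_chains = as.integer(n_chains),
                 param_names = colnames(draws), seed = seed,
                 accept_rates = accept_rates,
                 iterations = iterations, burn = burn),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", nrow(x$draws), "retained iterations,",
      x$n_chains, "chain(s),", ncol(x$draws), "parameter(s)\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (!is.null(x$accept_rates)) {
    cat("  acceptance:", paste(sprintf("%s=%.2f", names(x$accept_rates),
                                       x$accept_rates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Draw from the posterior by adaptive Metropolis-within-Gibbs
#'
#' Random-walk Metropolis updates are applied parameter by parameter on the
#' log scale (so positivity holds by construction; the Jacobian is included
#' in the target). During the first half of each chain — the burn-in, which
#' is discarded — proposal standard deviations are tuned in batches of 50
#' iterations towards an acceptance rate of 0.44, the standard optimum for
#' one-dimensional updates. Draws retained after burn-in from all chains are
#' concatenated with chain labels. Results are reproducible bit-for-bit for
#' a fixed (seed, spec, data, settings) combination.
#'
#' @param spec A `"model_spec"`.
#' @param table A `"catch_table"`; under the log scale, nights with `n = 0`
#'   are excluded from the likelihood with a message.
#' @param priors A `"prior_spec"`.
#' @param iterations Iterations per chain (first half discarded as burn-in).
#' @param chains Number of chains.
#' @param seed Integer seed controlling all randomness.
#' @param target_accept Per-parameter acceptance rate targeted during
#'   adaptation.
#' @return A `"posterior_draws"` object.
#' @export
sample_posterior <- function(spec, table, priors = prior_spec(),
                             iterations = 30000L, chains = 2L, seed = 1L,
                             target_accept = 0.44) {
  stopifnot(inherits(spec, "model_spec"), inherits(table, "catch_table"))
  iterations <- as.integer(iterations)
  if (length(iterations) != 1 || is.na(iterations) || iterations < 2) {
    stop("iterations must be an integer >= 2 (got ", iterations, ")")
  }
  if (chains < 1) stop("chains must be >= 1")
  ll <- make_loglik(spec, table)
  if (attr(ll, "n_used") == 0) {
    stop("no usable nights remain after excluding zero-catch nights")
  }
  if (attr(ll, "n_zero") > 0) {
    message("sample_posterior: excluded ", attr(ll, "n_zero"),
            " night(s) with n = 0 from the likelihood (",
            attr(ll, "n_impossible"), " of them with N > 0)")
  }
  pn <- param_names(spec)
  p <- length(pn)
  nb <- p - 1L
  bs <- priors$beta_shape; br <- priors$beta_rate
  ts <- priors$tau_shape; tr <- priors$tau_rate
  # Target on the log-parameter scale: posterior density times Jacobian.
  lp_log <- function(lth) {
    th <- exp(lth)
    v <- sum(dgamma(th[seq_len(nb)], shape = bs, rate = br, log = TRUE)) +
      dgamma(th[p], shape = ts, rate = tr, log = TRUE) + sum(lth) + ll(th)
    if (is.finite(v)) v else -Inf
  }

  burn <- iterations %/% 2L
  keep_n <- iterations - burn
  draws <- matrix(NA_real_, nrow = keep_n * chains, ncol = p,
                  dimnames = list(NULL, pn))
  chain_id <- integer(keep_n * chains)
  acc_post <- matrix(0, nrow = chains, ncol = p)

  set.seed(as.integer(seed))
  for (ch in seq_len(chains)) {
    lth <- rnorm(p, 0, 0.5)
    cur <- lp_log(lth)
    tries <- 0L
    while (!is.finite(cur) && tries < 100L) {
      lth <- rnorm(p, 0, 0.5)
      cur <- lp_log(lth)
      tries <- tries + 1L
    }
    if (!is.finite(cur)) stop("could not find a finite-density starting point")
    sd_prop <- rep(0.5, p)
    batch_acc <- numeric(p)
    batch_len <- 0L
    n_batch <- 0L
    acc_keep <- numeric(p)
    offset <- (ch - 1L) * keep_n
    for (it in seq_len(iterations)) {
      for (j in seq_len(p)) {
        prop <- lth
        prop[j] <- prop[j] + rnorm(1, 0, sd_prop[j])
        lp_new <- lp_log(prop)
        if (lp_new - cur > log(runif(1))) {
          lth <- prop
          cur <- lp_new
          batch_acc[j] <- batch_acc[j] + 1
          if (it > burn) acc_keep[j] <- acc_keep[j] + 1
        }
      }
      batch_len <- batch_len + 1L
      if (it <= burn && batch_len == 50L) {
        n_batch <- n_batch + 1L
        delta <- min(0.1, 1 / sqrt(n_batch))
        sd_prop <- sd_prop * exp(ifelse(batch_acc / 50 > target_accept,
                                        delta, -delta))
        batch_acc[] <- 0
        batch_len <- 0L
      }
      if (it > burn) draws[offset + it - burn, ] <- exp(lth)
    }
    acc_post[ch, ] <- acc_keep / keep_n
    chain_id[offset + seq_len(keep_n)] <- ch
  }
  acc <- setNames(colMeans(acc_post), pn)
  if (any(acc < 0.01)) {
    stop("sampler mixing failure: post-burn-in acceptance below 1% for ",
         paste(pn[acc < 0.01], collapse = ", "),
         "; increase iterations to allow adaptation to converge")
  }
  posterior_draws(draws, chain = chain_id, n_chains = chains, seed = seed,
                  accept_rates = acc, iterations = iterations, burn = burn)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Gelman-Rubin diagnostic computed on half-chains: each chain is split in
#' two, so trends within a chain inflate the between-sequence variance and
#' are flagged. Values near 1 indicate the chains agree; values above about
#' 1.05 suggest running longer.
#'
#' @param draws A `"posterior_draws"` object with at least two chains.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
rhat <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_chains < 2) {
    stop("R-hat requires chains >= 2; rerun sample_posterior() with more chains")
  }
  chains <- unique(draws$chain)
  seqs <- list()
  for (ch in chains) {
    idx <- which(draws$chain == ch)
    half <- length(idx) %/% 2L
    if (half < 2) stop("chains too short to split for R-hat")
    seqs <- c(seqs, list(idx[seq_len(half)], idx[(half + 1L):(2L * half)]))
  }
  m <- length(seqs)
  n <- min(lengths(seqs))
  out <- setNames(numeric(ncol(draws$draws)), colnames(draws$draws))
  for (j in seq_along(out)) {
    x <- vapply(seqs, function(ii) draws$draws[ii[seq_len(n)], j], numeric(n))
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    if (W == 0) {
      out[j] <- 1
    } else {
      var_plus <- (n - 1) / n * W + B / n
      out[j] <- sqrt(var_plus / W)
    }
  }
  out
}

#' Deviance information criterion for a fitted model
#'
#' The deviance is `D(theta) = -2 * log-likelihood` (likelihood term only).
#' `mean_deviance` averages `D` over the posterior draws;
#' `deviance_at_mean` evaluates `D` at the posterior means of the parameters
#' on the natural scale. The effective number of parameters is
#' `p_d = mean_deviance - deviance_at_mean` and
#' `dic = mean_deviance + p_d`. Lower DIC is better.
#'
#' @param draws A `"posterior_draws"` object fitted under `spec`.
#' @param spec A `"model_spec"`.
#' @param table The `"catch_table"` the model was fitted to.
#' @return An object of class `"dic_result"` with elements `dic`, `p_d`,
#'   `mean_deviance` and `deviance_at_mean`.
#' @export
compute_dic <- function(draws, spec, table) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(spec, "model_spec"))
  pn <- param_names(spec)
  if (!identical(colnames(draws$draws), pn)) {
    stop("draws parameterization (", paste(colnames(draws$draws), collapse = ", "),
         ") does not match the model spec (", paste(pn, collapse = ", "), ")")
  }
  ll <- make_loglik(spec, table)
  D <- apply(draws$draws, 1L, function(th) -2 * ll(th))
  mean_dev <- mean(D)
  theta_bar <- colMeans(draws$draws)
  dev_at_mean <- -2 * ll(theta_bar)
  p_d <- mean_dev - dev_at_mean
  structure(list(dic = mean_dev + p_d, p_d = p_d, mean_deviance = mean_dev,
                 deviance_at_mean = dev_at_mean),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, digits = 2, ...) {
  cat(sprintf("DIC: %.*f  (mean deviance %.*f, pD %.*f)\n",
              digits, x$dic, digits, x$mean_deviance, digits, x$p_d))
  invisible(x)
}
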