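# The four mean models and the Gamma-Poisson mixture likelihood.

#' Specify one of the four trap-to-HLC mean models
#'
#' The expected HLC count per night, `lambda_i`, is driven by the focal-trap
#' count `n_i` through one of four nested forms. Under the default
#' `scale = "log"` the covariates enter on the log scale, giving a
#' zero-intercept power law that honours the origin assumption (a night with
#' no trap catch predicts no HLC catch):
#'
#' * Model 1: `log(lambda) = beta1 * log(n)` — simple proportional efficiency.
#' * Model 2: `... + beta2 * log(n)^2` — intraspecific density dependence.
#' * Model 3: `... + beta2 * log(n) * log(1 + m)` — interspecific density
#'   dependence through the pooled other-taxa catch `m`.
#' * Model 4: `... + sum_k beta_k * log(n) * log(1 + s_k)` — per-taxon
#'   interspecific terms.
#'
#' With `lambda = 0` whenever `n = 0`. Under `scale = "raw"` the same
#' structures are applied literally on the untransformed counts
#' (`beta1 * n`, `beta2 * n^2`, `beta2 * n * m`, `beta_k * n * s_k`), which
#' grows exponentially in `n` and gives `lambda = 1` at `n = 0`; it is kept
#' for fidelity to the linear-predictor notation the models are usually
#' written in.
#'
#' @param model Integer 1--4.
#' @param scale `"log"` (default) or `"raw"`; see Details.
#' @param K Number of other-taxa groups available (columns of `s` in the
#'   catch table). Models 3 and 4 require `K >= 1`.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(model = 1L, scale = c("log", "raw"), K = 0L) {
  scale <- match.arg(scale)
  model <- as.integer(model)
  K <- as.integer(K)
  if (length(model) != 1 || !(model %in% 1:4)) stop("model must be 1, 2, 3 or 4")
  if (K < 0) stop("K must be non-negative")
  if (model >= 3 && K < 1) {
    stop("Model ", model, " requires at least one other-taxa group (K >= 1); ",
         "this table has none")
  }
  structure(list(model = model, scale = scale, K = K), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model", x$model, "on the", x$scale, "scale:",
      model_structure(x), "\n")
  invisible(x)
}

model_structure <- function(spec) {
  v <- if (spec$scale == "log") c("log(n)", "log(n)^2", "log(n)*log(1+m)",
                                  "log(n)*log(1+s_k)")
       else c("n", "n^2", "n*m", "n*s_k")
  switch(spec$model,
         paste0("log(lambda) = beta1*", v[1]),
         paste0("log(lambda) = beta1*", v[1], " + beta2*", v[2]),
         paste0("log(lambda) = beta1*", v[1], " + beta2*", v[3]),
         paste0("log(lambda) = beta1*", v[1], " + sum_k beta_k*", v[4]))
}

#' Prior specification for the model parameters
#'
#' Independent gamma priors. Every slope (`beta1`, `beta2`, each `beta_k`)
#' shares one gamma(shape, rate) prior whose positive support enforces a
#' positive trap-to-HLC relationship; the dispersion `tau` gets its own
#' diffuse gamma prior.
#'
#' @param beta_shape,beta_rate Gamma prior for the slopes (default 0.1, 0.1).
#' @param tau_shape,tau_rate Gamma prior for the dispersion (default
#'   0.01, 0.01).
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(beta_shape = 0.1, beta_rate = 0.1,
                       tau_shape = 0.01, tau_rate = 0.01) {
  vals <- c(beta_shape, beta_rate, tau_shape, tau_rate)
  if (anyNA(vals) || any(vals <= 0)) stop("all prior hyperparameters must be positive")
  structure(list(beta_shape = beta_shape, beta_rate = beta_rate,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "prior_spec")
}

#' Parameter names, in canonical order, for a model specification
#'
#' Slopes first (`beta1`, then `beta2` for Models 2--3, or `beta_s1` ...
#' `beta_sK` for Model 4), dispersion `tau` last.
#'
#' @param spec A `"model_spec"`.
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  betas <- switch(spec$model,
                  "beta1",
                  c("beta1", "beta2"),
                  c("beta1", "beta2"),
                  c("beta1", paste0("beta_s", seq_len(spec$K))))
  c(betas, "tau")
}

# Coerce a list/named vector of parameters into the canonical named vector.
as_model_params <- function(spec, params) {
  pn <- param_names(spec)
  if (is.list(params)) {
    if (!is.null(params$beta_k) && spec$model == 4) {
      bk <- params$beta_k
      params <- c(params[setdiff(names(params), "beta_k")],
                  setNames(as.list(bk), paste0("beta_s", seq_along(bk))))
    }
    params <- unlist(params)
  }
  if (is.null(names(params))) {
    if (length(params) != length(pn)) {
      stop("expected ", length(pn), " parameters (", paste(pn, collapse = ", "), ")")
    }
    names(params) <- pn
  }
  miss <- setdiff(pn, names(params))
  if (length(miss) > 0) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  params[pn]
}

# Design matrix for the slope terms, rows = nights of `table`.
model_design <- function(spec, table) {
  n <- table$n
  if (spec$scale == "log") {
    ln <- ifelse(n > 0, log(n), 0)
    X <- switch(spec$model,
                cbind(beta1 = ln),
                cbind(beta1 = ln, beta2 = ln^2),
                cbind(beta1 = ln, beta2 = ln * log1p(table$m)),
                cbind(beta1 = ln, ln * log1p(table$s)))
  } else {
    X <- switch(spec$model,
                cbind(beta1 = n),
                cbind(beta1 = n, beta2 = n^2),
                cbind(beta1 = n, beta2 = n * table$m),
                cbind(beta1 = n, n * table$s))
  }
  if (spec$model == 4) colnames(X) <- c("beta1", paste0("beta_s", seq_len(spec$K)))
  X
}

check_spec_table <- function(spec, table) {
  if (spec$model == 3 && table$K < 1) {
    stop("Model 3 requires the pooled other-taxa count m (no other-taxa groups in this table)")
  }
  if (spec$model == 4 && table$K < 1) {
    stop("Model 4 requires per-taxon counts s (no other-taxa groups in this table)")
  }
  if (spec$model == 4 && spec$K != table$K) {
    stop("spec declares K = ", spec$K, " but the table has K = ", table$K)
  }
  invisible(TRUE)
}

#' Expected HLC counts per night under a mean model
#'
#' Evaluates `lambda_i` for every night of a catch table at fixed parameter
#' values. Under the log scale, `lambda = 0` whenever `n = 0` (the origin
#' assumption); under the raw scale the linear predictor is exponentiated
#' literally.
#'
#' @param spec A `"model_spec"`.
#' @param params Parameters as a named vector or list (`beta1`, `beta2`,
#'   `beta_k`/`beta_s1..K`, `tau`; `tau` may be omitted here).
#' @param table A `"catch_table"`.
#' @return Numeric vector of non-negative `lambda_i`, one per night.
#' @examples
#' tab <- catch_table(N = c(7L, 0L), n = c(10L, 0L))
#' build_lambda(model_spec(1), c(beta1 = 2, tau = 1), tab) # 100, 0
#' @export
build_lambda <- function(spec, params, table) {
  stopifnot(inherits(spec, "model_spec"), inherits(table, "catch_table"))
  check_spec_table(spec, table)
  if (is.list(params) && is.null(params$tau)) params$tau <- 1
  p <- as_model_params(spec, params)
  X <- model_design(spec, table)
  betas <- p[colnames(X)]
  lam <- exp(drop(X %*% betas))
  if (spec$scale == "log") lam[table$n == 0] <- 0
  unname(lam)
}

#' Log-pmf of the Gamma-Poisson mixture (negative binomial) count model
#'
#' The observation model is `N ~ Poisson(theta * lambda)` with multiplicative
#' noise `theta ~ Gamma(tau * lambda, tau * lambda)` (shape, rate), whose
#' marginal is negative binomial with size `tau * lambda` and success
#' probability `tau / (tau + 1)`: mean `lambda`, variance
#' `lambda * (1 + 1/tau)`. At `lambda = 0` the count is degenerate at zero.
#'
#' @param N Non-negative integer count(s).
#' @param lambda Non-negative mean(s).
#' @param tau Positive dispersion; larger values approach the Poisson.
#' @return Log-probability, vectorised over the arguments.
#' @examples
#' negbin_logpmf(0, 1, 1) # log(1/2)
#' @export
negbin_logpmf <- function(N, lambda, tau) {
  if (anyNA(N) || any(N < 0) || any(N != round(N))) {
    stop("N must be a non-negative integer")
  }
  if (anyNA(tau) || any(tau <= 0)) stop("tau must be positive")
  if (anyNA(lambda) || any(lambda < 0)) stop("lambda must be non-negative")
  len <- max(length(N), length(lambda), length(tau))
  N <- rep_len(N, len); lambda <- rep_len(lambda, len); tau <- rep_len(tau, len)
  out <- numeric(len)
  z <- lambda == 0
  out[z] <- ifelse(N[z] == 0, 0, -Inf)
  if (any(!z)) {
    out[!z] <- dnbinom(N[!z], size = tau[!z] * lambda[!z],
                       prob = tau[!z] / (tau[!z] + 1), log = TRUE)
  }
  out
}

#' Joint log-prior density of the model parameters
#'
#' Sum of independent gamma log-densities: one shared gamma prior over every
#' slope and a separate gamma prior for the dispersion `tau`. Any
#' non-positive parameter is outside the support and yields `-Inf` (it is
#' not an error, so samplers can reject such proposals).
#'
#' @param params Named vector or list of parameters including `tau`.
#' @param priors A `"prior_spec"`.
#' @param spec Optional `"model_spec"` used to canonicalise `params`.
#' @return Log-density (scalar), `-Inf` outside the positive orthant.
#' @export
log_prior <- function(params, priors = prior_spec(), spec = NULL) {
  stopifnot(inherits(priors, "prior_spec"))
  p <- if (!is.null(spec)) as_model_params(spec, params) else unlist(params)
  if (is.null(names(p)) || !("tau" %in% names(p))) {
    stop("params must be named and include tau")
  }
  if (anyNA(p) || any(p <= 0)) return(-Inf)
  betas <- p[names(p) != "tau"]
  sum(dgamma(betas, shape = priors$beta_shape, rate = priors$beta_rate,
             log = TRUE)) +
    dgamma(p[["tau"]], shape = priors$tau_shape, rate = priors$tau_rate,
           log = TRUE)
}

# Fast likelihood closure over the nights of `table`.
# Under the log scale, nights with n = 0 are excluded from the likelihood:
# they contribute 0 when N = 0 and are impossible (zero likelihood) when
# N > 0 under the origin constraint. attr(f, "n_zero") counts excluded
# nights, attr(f, "n_impossible") those with N > 0.
make_loglik <- function(spec, table) {
  check_spec_table(spec, table)
  keep <- if (spec$scale == "log") table$n > 0 else rep(TRUE, length(table$n))
  n_zero <- sum(!keep)
  n_imposs <- if (spec$scale == "log") sum(table$n == 0 & table$N > 0) else 0L
  sub <- table[keep]
  X <- model_design(spec, sub)
  N <- sub$N
  nb <- ncol(X)
  f <- function(par) {
    betas <- par[seq_len(nb)]
    tau <- par[[nb + 1L]]
    lam <- exp(drop(X %*% betas))
    if (!all(is.finite(lam))) return(-Inf)
    ll <- sum(dnbinom(N, size = tau * lam, prob = tau / (tau + 1), log = TRUE))
    if (is.finite(ll)) ll else -Inf
  }
  attr(f, "n_zero") <- n_zero
  attr(f, "n_impossible") <- n_imposs
  attr(f, "n_used") <- length(N)
  f
}

# Lambda-evaluating closure over ALL nights of `table` (origin rule applied).
make_lambda_fun <- function(spec, table) {
  check_spec_table(spec, table)
  X <- model_design(spec, table)
  zero <- if (spec$scale == "log") table$n == 0 else rep(FALSE, length(table$n))
  nb <- ncol(X)
  function(par) {
    lam <- exp(drop(X %*% par[seq_len(nb)]))
    lam[zero] <- 0
    lam
  }
}

#' Log-posterior density (likelihood plus prior)
#'
#' Sums [negbin_logpmf()] over the nights of the table (under the log scale,
#' nights with `n = 0` are excluded: they carry no information when `N = 0`
#' and zero likelihood otherwise) and adds [log_prior()]. An empty table
#' returns the prior alone.
#'
#' @param params Named vector or list of parameters including `tau`.
#' @param spec A `"model_spec"`.
#' @param table A `"catch_table"`.
#' @param priors A `"prior_spec"`.
#' @return Log-density (scalar); `-Inf` outside the parameter support.
#' @export
log_posterior <- function(params, spec, table, priors = prior_spec()) {
  p <- as_model_params(spec, params)
  lp <- log_prior(p, priors)
  if (!is.finite(lp)) return(lp)
  ll <- make_loglik(spec, table)(p)
  lp + ll
}
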