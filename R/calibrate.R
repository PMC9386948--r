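# HLC-equivalent prediction, lookup tables and power-law curve utilities.

#' Posterior prediction of HLC-equivalents for new trap counts
#'
#' For every posterior draw, the expected HLC catch `lambda(n_new)` is
#' evaluated through the fitted mean model; the posterior mean and
#' equal-tailed interval of those values are returned. With
#' `interval = "predictive"` the interval instead covers a new night's
#' count, drawn from the Gamma-Poisson mixture for each posterior draw
#' (much wider, since it adds observation noise to parameter uncertainty).
#' Under the origin-constrained log scale, `n_new = 0` returns `(0, 0, 0)`.
#'
#' @param draws A `"posterior_draws"` object fitted under `spec`.
#' @param spec The `"model_spec"` the draws were generated under.
#' @param n_new Vector of non-negative integer trap counts.
#' @param m Reference pooled other-taxa count (required for Model 3).
#' @param s Reference per-taxon counts, length `K` (required for Model 4).
#' @param interval `"credible"` (default) or `"predictive"`.
#' @param level Interval coverage (default 0.95).
#' @return A data frame with one row per `n_new` value and columns `n`,
#'   `mean`, `lo`, `hi`.
#' @export
predict_hlc <- function(draws, spec, n_new, m = NULL, s = NULL,
                        interval = c("credible", "predictive"),
                        level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(spec, "model_spec"))
  interval <- match.arg(interval)
  if (anyNA(n_new) || any(n_new < 0) || any(n_new != round(n_new))) {
    stop("n_new must be non-negative integer counts")
  }
  missing_terms <- character()
  if (spec$model == 3 && is.null(m)) missing_terms <- "m (pooled other-taxa count)"
  if (spec$model == 4 && is.null(s)) {
    missing_terms <- paste0("s (", spec$K, " per-taxon other-group counts)")
  }
  if (length(missing_terms) > 0) {
    stop("Model ", spec$model, " predictions require reference covariate(s): ",
         paste(missing_terms, collapse = ", "))
  }
  len <- length(n_new)
  if (spec$model == 4) {
    s <- as.integer(s)
    if (length(s) != spec$K) stop("s must have length K = ", spec$K)
  }
  # A minimal table-shaped holder for the prediction grid; the container
  # invariant linking m to s does not apply to fixed reference covariates.
  ptab <- structure(list(
    night_id = paste0("grid_", seq_len(len)),
    N = integer(len), n = as.integer(n_new),
    m = if (!is.null(m)) rep(as.integer(m), len) else integer(len),
    s = if (spec$model == 4) matrix(rep(s, each = len), nrow = len)
        else matrix(integer(), nrow = len, ncol = 0),
    K = if (spec$model == 4) spec$K else 0L),
    class = "catch_table")
  X <- model_design(spec, ptab)
  zero <- if (spec$scale == "log") ptab$n == 0 else rep(FALSE, len)
  nb <- ncol(X)
  lf <- function(par) {
    lam <- exp(drop(X %*% par[seq_len(nb)]))
    lam[zero] <- 0
    lam
  }
  B <- draws$draws
  lam <- matrix(NA_real_, nrow = nrow(B), ncol = len)
  for (r in seq_len(nrow(B))) lam[r, ] <- lf(B[r, ])
  alpha <- (1 - level) / 2
  mean_hlc <- colMeans(lam)
  if (interval == "credible") {
    qs <- apply(lam, 2, quantile, probs = c(alpha, 1 - alpha))
  } else {
    tau <- B[, "tau"]
    Nmat <- matrix(0, nrow = nrow(B), ncol = len)
    for (j in seq_len(len)) {
      pos <- lam[, j] > 0
      if (any(pos)) {
        Nmat[pos, j] <- rnbinom(sum(pos), size = tau[pos] * lam[pos, j],
                                prob = tau[pos] / (tau[pos] + 1))
      }
    }
    qs <- apply(Nmat, 2, quantile, probs = c(alpha, 1 - alpha))
  }
  data.frame(n = n_new, mean = mean_hlc, lo = qs[1, ], hi = qs[2, ])
}

#' Build an HLC-equivalent lookup table
#'
#' One row per grid value of the collected count, with the posterior-mean
#' HLC-equivalent and 95% credible bounds from [predict_hlc()]. Displayed
#' cells are rounded to the nearest integer; unrounded values are retained
#' in `attr(, "unrounded")`.
#'
#' @param object An `"hlc_fit"` or `"posterior_draws"` object.
#' @param ... Passed on to methods.
#' @return A data frame of class `"hlc_lookup"` with columns `collected`,
#'   `expected_hlc`, `lo95`, `hi95`.
#' @export
make_lookup_table <- function(object, ...) UseMethod("make_lookup_table")

#' @rdname make_lookup_table
#' @param spec The `"model_spec"` the draws were generated under.
#' @param grid Strictly increasing positive integer counts (default
#'   10, 20, ..., 100).
#' @param m,s Reference covariates for Models 3--4; see [predict_hlc()].
#' @param taxon,trap Labels stored with the table.
#' @param level Credible level (default 0.95).
#' @param interval `"credible"` or `"predictive"`.
#' @export
make_lookup_table.posterior_draws <- function(object, spec,
                                              grid = seq(10L, 100L, by = 10L),
                                              m = NULL, s = NULL,
                                              taxon = NA_character_,
                                              trap = NA_character_,
                                              level = 0.95,
                                              interval = c("credible", "predictive"),
                                              ...) {
  interval <- match.arg(interval)
  grid <- as.integer(grid)
  if (length(grid) == 0) stop("grid must be non-empty")
  if (any(grid <= 0)) stop("grid must contain positive counts")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  pr <- predict_hlc(object, spec, grid, m = m, s = s, interval = interval,
                    level = level)
  out <- data.frame(collected = grid,
                    expected_hlc = as.integer(round(pr$mean)),
                    lo95 = as.integer(round(pr$lo)),
                    hi95 = as.integer(round(pr$hi)))
  attr(out, "unrounded") <- pr
  attr(out, "taxon") <- taxon
  attr(out, "trap") <- trap
  attr(out, "model") <- spec$model
  attr(out, "interval") <- interval
  class(out) <- c("hlc_lookup", "data.frame")
  out
}

#' @rdname make_lookup_table
#' @export
make_lookup_table.hlc_fit <- function(object, grid = seq(10L, 100L, by = 10L),
                                      m = NULL, s = NULL, level = 0.95,
                                      interval = c("credible", "predictive"),
                                      ...) {
  interval <- match.arg(interval)
  if (object$spec$model == 3 && is.null(m)) m <- median(object$table$m)
  if (object$spec$model == 4 && is.null(s)) s <- apply(object$table$s, 2, median)
  make_lookup_table(object$draws, spec = object$spec, grid = grid, m = m,
                    s = s, taxon = object$table$taxon,
                    trap = object$table$trap, level = level,
                    interval = interval)
}

#' @export
print.hlc_lookup <- function(x, ...) {
  cat("HLC-equivalent lookup table")
  tx <- attr(x, "taxon"); tr <- attr(x, "trap")
  if (!is.na(tr)) cat(" —", tr)
  if (!is.na(tx)) cat(",", tx)
  cat(" (Model ", attr(x, "model"), ", ", attr(x, "interval"),
      " intervals)\n", sep = "")
  cells <- sprintf("%d (%d-%d)", x$expected_hlc, x$lo95, x$hi95)
  print(data.frame(collected = x$collected, expected_HLC = cells),
        row.names = FALSE)
  invisible(x)
}

#' Fit a zero-intercept power-law curve to published conversion pairs
#'
#' Given pairs of (collected count, expected HLC-equivalent) — for example
#' the rows of a published conversion table for the linear calibration model
#' — estimates the power-law exponent by zero-intercept least squares on the
#' log-log scale:
#' `beta1_hat = sum(log(n) * log(N)) / sum(log(n)^2)`. The fitted curve is
#' `N_hat(n) = n^beta1_hat`, the same functional form as Model 1 under the
#' log covariate scale, which makes this the natural validation bridge
#' between a fitted posterior and printed conversion values.
#'
#' @param collected Strictly positive counts, or a two-column data frame /
#'   matrix of (collected, expected) pairs.
#' @param expected Strictly positive HLC-equivalents (omit when `collected`
#'   is two-column).
#' @return An object of class `"power_curve"` with elements `beta1`,
#'   `pairs` and `residuals` (log-scale).
#' @examples
#' pc <- fit_published_curve(c(2, 4, 8, 16), c(2, 4, 8, 16)^1.5)
#' pc$beta1 # exactly 1.5
#' predict(pc, 100)
#' @export
fit_published_curve <- function(collected, expected = NULL) {
  if (is.null(expected)) {
    pairs <- as.data.frame(collected)
    if (ncol(pairs) < 2) stop("provide expected values or a two-column object")
    collected <- pairs[[1]]
    expected <- pairs[[2]]
  }
  if (length(collected) != length(expected)) {
    stop("collected and expected must have equal length")
  }
  if (length(collected) < 2) stop("need at least 2 pairs")
  if (anyNA(collected) || anyNA(expected) ||
      any(collected <= 0) || any(expected <= 0)) {
    stop("all pairs must be strictly positive")
  }
  ln <- log(collected)
  lN <- log(expected)
  beta1 <- sum(ln * lN) / sum(ln^2)
  structure(list(beta1 = beta1,
                 pairs = data.frame(collected = collected, expected = expected),
                 residuals = lN - beta1 * ln),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, digits = 4, ...) {
  cat("Zero-intercept power-law calibration curve: N_hat = n^",
      round(x$beta1, digits), "\n", sep = "")
  cat("  fitted to", nrow(x$pairs), "pairs; log-scale RMS residual",
      signif(sqrt(mean(x$residuals^2)), 3), "\n")
  invisible(x)
}

#' Predict from a fitted power-law curve
#'
#' @param object A `"power_curve"`.
#' @param n_new Non-negative counts; `n_new = 0` maps to 0 (origin).
#' @param ... Unused.
#' @return Predicted HLC-equivalents.
#' @export
predict.power_curve <- function(object, n_new, ...) {
  unname(n_new^object$beta1)
}

#' Published reference conversion table bundled with the package
#'
#' Posterior-mean HLC-equivalents with 95% credible bounds for the linear
#' calibration model (Model 1), as published for a year-long Tanzanian
#' evaluation of six outdoor traps against the HLC, for collected counts
#' 10, 20, ..., 100 and three taxa (An. arabiensis, An. funestus, Culex
#' spp.). Used to validate the curve-fitting utilities against printed
#' values (see [fit_published_curve()]).
#'
#' @param taxon Optional filter: one of `"an_arabiensis"`, `"an_funestus"`,
#'   `"culex"`.
#' @param trap Optional filter: one of the non-HLC [trap_codes].
#' @return A data frame with columns `taxon`, `trap`, `collected`, `hlc`,
#'   `hlc_lo`, `hlc_hi`.
#' @export
reference_conversions <- function(taxon = NULL, trap = NULL) {
  path <- system.file("extdata", "hlc_reference_conversions.csv",
                      package = "trapcal", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(taxon)) ref <- ref[ref$taxon == taxon, ]
  if (!is.null(trap)) ref <- ref[ref$trap == normalize_trap(trap), ]
  rownames(ref) <- NULL
  ref
}
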