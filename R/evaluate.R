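# Goodness of fit, cross-validation and multi-model comparison.

#' Pseudo-R-squared between observed and fitted counts
#'
#' Defined as 100 times the squared Pearson correlation between observed
#' counts and (posterior-mean) fitted values. When the fitted values are
#' constant the correlation is undefined and 0 is returned by convention.
#' This definition is invariant to any positive affine rescaling of the
#' fitted values.
#'
#' @param observed,fitted Numeric vectors of equal length (at least 2).
#' @return A percentage in `[0, 100]`.
#' @examples
#' pseudo_r2(c(1, 2, 3), c(1, 2, 4)) # ~96.43
#' @export
pseudo_r2 <- function(observed, fitted) {
  if (length(observed) != length(fitted)) {
    stop("observed and fitted must have equal length")
  }
  if (length(observed) < 2) stop("need at least 2 observations")
  if (sd(fitted) == 0 || sd(observed) == 0) return(0)
  100 * cor(observed, fitted)^2
}

#' Held-out root-mean-square error under a random train/test split
#'
#' Nights are split uniformly at random (75% training by default) with the
#' given seed; the model is fitted on the training nights and the RMSE of
#' the posterior-mean predictions `lambda_hat` is computed on the test
#' nights: `sqrt(mean((N_i - lambda_hat_i)^2))`. The same seed reproduces
#' the same split, fit and RMSE.
#'
#' @param table A `"catch_table"`.
#' @param model,scale,priors Model choice; see [hlc_calibrate()].
#' @param train_fraction Fraction of nights used for training.
#' @param seed Seed controlling the split and the sampler.
#' @param iterations,chains Sampler settings for the training fit.
#' @return The test-set RMSE (non-negative scalar).
#' @export
train_test_rmse <- function(table, model = 1, scale = c("log", "raw"),
                            priors = prior_spec(), train_fraction = 0.75,
                            seed = 1, iterations = 30000, chains = 2) {
  stopifnot(inherits(table, "catch_table"))
  scale <- match.arg(scale)
  nights <- length(table$N)
  n_train <- round(train_fraction * nights)
  if (n_train < 1 || n_train >= nights) {
    stop("train fraction ", train_fraction, " leaves an empty split for ",
         nights, " nights")
  }
  set.seed(as.integer(seed))
  idx <- sort(sample.int(nights, n_train))
  train <- table[idx]
  test <- table[setdiff(seq_len(nights), idx)]
  spec <- model_spec(model, scale, K = table$K)
  dr <- sample_posterior(spec, train, priors, iterations = iterations,
                         chains = chains, seed = seed)
  lam_hat <- posterior_mean_lambda(dr, spec, test)
  sqrt(mean((test$N - lam_hat)^2))
}

#' Fit and compare several mean models on the same catch table
#'
#' Each model is fitted with identical priors, sampler settings and seed;
#' the comparison reports pseudo-R-squared, DIC, the DIC difference from
#' the best model (`dDIC`, with ties broken towards the lowest model id)
#' and, optionally, the held-out RMSE. An individual fit failure flags the
#' row rather than dropping it.
#'
#' @param table A `"catch_table"`.
#' @param models Integer vector of at least two model ids from 1--4.
#' @param scale,priors,iterations,chains,seed See [hlc_calibrate()].
#' @param rmse Compute the train/test RMSE per model (doubles the fitting
#'   work)? Default `TRUE`.
#' @param train_fraction Training fraction for the RMSE split.
#' @return A data frame of class `"model_comparison"` with columns `model`,
#'   `R2`, `DIC`, `dDIC`, `RMSE` and `note`, ordered by model id. The fitted
#'   objects are attached as `attr(, "fits")`.
#' @export
compare_models <- function(table, models = 1:4, scale = c("log", "raw"),
                           priors = prior_spec(), iterations = 30000,
                           chains = 2, seed = 1, rmse = TRUE,
                           train_fraction = 0.75) {
  stopifnot(inherits(table, "catch_table"))
  scale <- match.arg(scale)
  models <- sort(unique(as.integer(models)))
  if (length(models) < 2) stop("need at least two model specifications to compare")
  rows <- vector("list", length(models))
  fits <- vector("list", length(models))
  for (i in seq_along(models)) {
    mdl <- models[i]
    res <- tryCatch({
      fit <- hlc_calibrate(table, model = mdl, scale = scale, priors = priors,
                           iterations = iterations, chains = chains,
                           seed = seed)
      rm_val <- if (rmse) {
        train_test_rmse(table, model = mdl, scale = scale, priors = priors,
                        train_fraction = train_fraction, seed = seed,
                        iterations = iterations, chains = chains)
      } else NA_real_
      fits[[i]] <- fit
      data.frame(model = mdl, R2 = fit$pseudo_r2, DIC = fit$dic$dic,
                 RMSE = rm_val, note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("Model ", mdl, " failed: ", conditionMessage(e), call. = FALSE)
      data.frame(model = mdl, R2 = NA_real_, DIC = NA_real_, RMSE = NA_real_,
                 note = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$DIC)
  out$dDIC <- NA_real_
  if (any(ok)) {
    best_dic <- min(out$DIC[ok])
    out$dDIC[ok] <- out$DIC[ok] - best_dic
    zero_rows <- which(ok & out$dDIC == 0)
    if (length(zero_rows) > 1) {
      message("compare_models: DIC tie between models ",
              paste(out$model[zero_rows], collapse = ", "),
              "; model ", out$model[zero_rows[1]], " reported as best")
    }
    attr(out, "best") <- out$model[zero_rows[1]]
  }
  out <- out[, c("model", "R2", "DIC", "dDIC", "RMSE", "note")]
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 2, ...) {
  cat("Model comparison (lower DIC is better)\n")
  df <- as.data.frame(x)
  df$R2 <- round(df$R2, digits)
  df$DIC <- round(df$DIC, digits)
  df$dDIC <- round(df$dDIC, digits)
  df$RMSE <- round(df$RMSE, digits)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "best"))) cat("Best model:", attr(x, "best"), "\n")
  invisible(x)
}
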