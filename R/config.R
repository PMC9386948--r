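# Serialization: model/prior configs (YAML or JSON) and fit results (JSON).

#' Write a model and prior configuration to YAML or JSON
#'
#' The config block uses the keys `model`, `covariate_scale`, optionally
#' `K`, and `priors: beta: {shape, rate}, tau: {shape, rate}`.
#'
#' @param path Output path; a `.json` extension selects JSON, anything else
#'   YAML.
#' @param spec A `"model_spec"`.
#' @param priors A `"prior_spec"`.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(path, spec, priors = prior_spec()) {
  stopifnot(inherits(spec, "model_spec"), inherits(priors, "prior_spec"))
  cfg <- list(model = spec$model, covariate_scale = spec$scale,
              priors = list(beta = list(shape = priors$beta_shape,
                                        rate = priors$beta_rate),
                            tau = list(shape = priors$tau_shape,
                                       rate = priors$tau_rate)))
  if (spec$K > 0) cfg$K <- spec$K
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Read a model and prior configuration from YAML or JSON
#'
#' @param path Path to a file written by [write_model_config()] (or hand
#'   authored with the same keys).
#' @return A list with elements `spec` (a `"model_spec"`) and `priors`
#'   (a `"prior_spec"`).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$model)) stop("config is missing the 'model' key")
  pr <- cfg$priors
  priors <- prior_spec(
    beta_shape = if (!is.null(pr$beta$shape)) pr$beta$shape else 0.1,
    beta_rate = if (!is.null(pr$beta$rate)) pr$beta$rate else 0.1,
    tau_shape = if (!is.null(pr$tau$shape)) pr$tau$shape else 0.01,
    tau_rate = if (!is.null(pr$tau$rate)) pr$tau$rate else 0.01)
  spec <- model_spec(cfg$model,
                     scale = if (!is.null(cfg$covariate_scale)) cfg$covariate_scale else "log",
                     K = if (!is.null(cfg$K)) cfg$K else 0L)
  list(spec = spec, priors = priors)
}

#' Serialize a calibration fit to JSON
#'
#' Writes posterior means, 2.5/50/97.5 percentiles per parameter, DIC and
#' pD, pseudo-R-squared, R-hat, seed and sampler settings.
#'
#' @param fit An `"hlc_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hlc_fit"))
  sm <- fit$summary
  params <- lapply(rownames(sm), function(p) {
    list(mean = sm[p, "mean"], sd = sm[p, "sd"], q2.5 = sm[p, "2.5%"],
         q50 = sm[p, "50%"], q97.5 = sm[p, "97.5%"],
         rhat = if (!is.null(fit$rhat)) fit$rhat[[p]] else NULL)
  })
  names(params) <- rownames(sm)
  out <- list(model = fit$spec$model, covariate_scale = fit$spec$scale,
              taxon = fit$table$taxon, trap = fit$table$trap,
              nights = length(fit$table$N), parameters = params,
              dic = fit$dic$dic, p_d = fit$dic$p_d,
              pseudo_r2 = fit$pseudo_r2,
              settings = fit$settings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
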