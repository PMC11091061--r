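# Variance-partition diagnostics for the mixed-model ladder: intraclass
# correlation (ICC), proportional change in variance (PCV), the variance
# partition coefficient (VPC) of random-slope models, marginal/conditional
# R-squared and the deviance-based information criteria.

#' Intraclass correlation
#'
#' `ICC = var_plant / (var_plant + var_sample)`: the share of the total
#' variance sitting at the plant (grouping) level.
#'
#' @param var_plant between-plant (intercept) variance, or a fitted
#'   [amf_mlm()] object.
#' @param var_sample between-sample (residual) variance; ignored when a fit
#'   is supplied.
#' @return proportion in `[0, 1]`; `NA` with a warning when both variances
#'   are zero.
#' @export
icc <- function(var_plant, var_sample = NULL) {
  if (inherits(var_plant, "amf_mlm")) {
    var_sample <- var_plant$vcomp[["var_e"]]
    var_plant <- var_plant$vcomp[["var_u0"]]
  }
  stopifnot(var_plant >= 0, var_sample >= 0)
  tot <- var_plant + var_sample
  if (tot == 0) {
    warning("both variance components zero; ICC undefined")
    return(NA_real_)
  }
  var_plant / tot
}

#' Proportional change in variance
#'
#' `PCV = (var_ref - var_new) / var_ref`, the share of a reference (null)
#' model's variance component accounted for by a richer model; negative when
#' the component grows.
#'
#' @param var_ref variance component in the reference model (must be > 0).
#' @param var_new the same component in the comparison model.
#' @return signed proportion; `NA` with a warning when `var_ref` is 0.
#' @export
pcv <- function(var_ref, var_new) {
  stopifnot(var_ref >= 0, var_new >= 0)
  if (var_ref == 0) {
    warning("reference variance is zero; PCV undefined")
    return(NA_real_)
  }
  (var_ref - var_new) / var_ref
}

#' PCV of both levels between two fits
#'
#' @param ref,fit reference and comparison [amf_mlm()] fits.
#' @return named vector `c(plant = , sample = )`.
#' @export
pcv_between <- function(ref, fit) {
  stopifnot(inherits(ref, "amf_mlm"), inherits(fit, "amf_mlm"))
  c(plant = pcv(ref$vcomp[["var_u0"]], fit$vcomp[["var_u0"]]),
    sample = pcv(ref$vcomp[["var_e"]], fit$vcomp[["var_e"]]))
}

#' Variance partition coefficient at a covariate value
#'
#' For a random-slope model the plant-level variance is the quadratic
#' `sigma^2_u0 + sigma^2_u1 x^2 + 2 sigma_u0u1 x` in the slope covariate
#' `x`, and
#' `VPC(x) = (sigma^2_u0 + sigma^2_u1 x^2 + 2 sigma_u0u1 x) /
#'           (sigma^2_u0 + sigma^2_u1 x^2 + 2 sigma_u0u1 x + sigma^2_e)`.
#' With no random slope this reduces to the ICC for every `x`.
#'
#' @param fit an [amf_mlm()] fit, or a named vector/list with elements
#'   `var_u0`, `var_u1`, `cov_u0u1`, `var_e`.
#' @param x covariate value(s); vectorized.
#' @return proportion(s) in `[0, 1]`.
#' @export
vpc_at <- function(fit, x) {
  v <- if (inherits(fit, "amf_mlm")) fit$vcomp else unlist(fit)
  need <- c("var_u0", "var_u1", "cov_u0u1", "var_e")
  if (!all(need %in% names(v))) stop("need components: ",
                                     paste(need, collapse = ", "))
  if (v[["var_u0"]] < 0 || v[["var_u1"]] < 0 || v[["var_e"]] < 0 ||
      v[["cov_u0u1"]]^2 > v[["var_u0"]] * v[["var_u1"]] * (1 + 1e-8))
    stop("variance parameters are not positive semi-definite")
  num <- v[["var_u0"]] + v[["var_u1"]] * x^2 + 2 * v[["cov_u0u1"]] * x
  num / (num + v[["var_e"]])
}

#' Marginal and conditional R-squared
#'
#' Marginal R2 is the share of variance explained by the fixed effects,
#' conditional R2 the share explained by fixed plus random effects:
#' `marginal = var_fixed / (var_fixed + var_random + var_e)`,
#' `conditional = (var_fixed + var_random) / (var_fixed + var_random +
#' var_e)`.  For random-intercept fits `var_random = sigma^2_u0`; for
#' random-slope fits it is the observation-averaged quadratic
#' `sigma^2_u0 + sigma^2_u1 mean(x^2) + 2 sigma_u0u1 mean(x)`.
#'
#' @param fit an [amf_mlm()] fit.
#' @return named vector `c(marginal = , conditional = )`.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "amf_mlm"))
  v <- fit$vcomp
  var_random <- v[["var_u0"]]
  if (!is.null(fit$random_slope)) {
    x <- fit$slope_x
    var_random <- var_random + v[["var_u1"]] * mean(x^2) +
      2 * v[["cov_u0u1"]] * mean(x)
  }
  denom <- fit$var_fixed + var_random + v[["var_e"]]
  if (denom <= 0) {
    warning("zero total variance; R-squared undefined")
    return(c(marginal = NA_real_, conditional = NA_real_))
  }
  c(marginal = fit$var_fixed / denom,
    conditional = (fit$var_fixed + var_random) / denom)
}

#' Deviance-based information criteria
#'
#' `deviance = -2 logLik`, `AIC = deviance + 2 k`,
#' `BIC = deviance + k log(n)` with `k` the fit's parameter count (fixed
#' effects plus distinct variance/covariance parameters).
#'
#' @param fit an [amf_mlm()] fit.
#' @return named vector `c(aic = , bic = , deviance = )`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "amf_mlm"))
  dev <- -2 * fit$loglik
  k <- fit$n_params
  c(aic = dev + 2 * k, bic = dev + k * log(fit$n_obs), deviance = dev)
}

#' Likelihood ratio test of nested mixed models
#'
#' Compares two fits of the same data whose parameters nest.  Both models
#' are (re)fitted by ML before comparison, since REML likelihoods are not
#' comparable across fixed-effect structures.  The statistic is the
#' deviance difference, referred to a chi-squared distribution with the
#' difference in parameter counts as degrees of freedom.
#'
#' @param nested,full the smaller and larger [amf_mlm()] fits.
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "amf_mlm"), inherits(full, "amf_mlm"))
  nested <- refit_method(nested, "ML")
  full <- refit_method(full, "ML")
  if (nested$n_obs != full$n_obs)
    stop("models were fitted to different numbers of observations")
  stat <- (-2 * nested$loglik) - (-2 * full$loglik)
  df <- full$n_params - nested$n_params
  if (df < 0L) stop("'full' has fewer parameters than 'nested'")
  if (stat < -1e-6)
    stop("negative LRT statistic: models do not nest or a fit failed")
  stat <- max(stat, 0)
  p <- if (df == 0L) as.numeric(stat <= 1e-8) else
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
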