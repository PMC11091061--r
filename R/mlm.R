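# Two-level mixed linear models for colonization phenotypes.
#
# The model ladder used throughout is
#   y_ij = X_ij beta + u_0i [+ u_1i x_1ij] + e_ij,
# with plants i as the grouping level, root samples j nested in plants,
# (u_0i, u_1i) jointly normal with variances sigma^2_u0, sigma^2_u1 and
# covariance sigma_u0u1, and e_ij ~ N(0, sigma^2_e).  Likelihood
# maximization is delegated to lme4; this surface adds the bookkeeping the
# variance-partition diagnostics need (a fixed parameter-count convention,
# the empirical variance of the fixed-effect predictor, stored slope
# covariate moments) and the deviance convention deviance = -2 logLik.

#' Fit a two-level mixed linear model
#'
#' Fits a random-intercept (optionally random-intercept + one random slope)
#' Gaussian mixed model by REML or ML.  The parameter count used for
#' AIC/BIC is the number of fixed effects plus the number of distinct
#' variance/covariance parameters (intercept variance, residual variance,
#' and for slope models the slope variance and intercept-slope covariance).
#'
#' @param formula fixed-effects formula, e.g.
#'   `total_pct_colonization ~ region + arb_count_scaled`.
#' @param data data.frame with the response, covariates and grouping column.
#' @param group name of the grouping (plant) column.
#' @param random_slope name of one covariate given a plant-level random
#'   slope, or `NULL` for a random intercept only.
#' @param method `"REML"` (default; variance components) or `"ML"`
#'   (deviance comparisons across fixed-effect structures).
#' @return an object of class `amf_mlm`: fixed-effect estimates and
#'   standard errors, variance components (`var_u0`, `var_u1`, `cov_u0u1`,
#'   `var_e`), `var_fixed` (empirical variance of the fixed-effect linear
#'   predictor), log-likelihood, `n_obs`, `n_params`, convergence flags and
#'   the underlying `lme4` fit.
#' @seealso [icc()], [vpc_at()], [r_squared()], [information_criteria()],
#'   [likelihood_ratio_test()], [build_model_ladder()]
#' @examples
#' d <- simulate_mlm_dataset(sim_mlm_params(I = 12), seed = 1)
#' fit <- amf_mlm(y ~ region + arb_count_scaled, d)
#' summary(fit)
#' @export
amf_mlm <- function(formula, data, group = "plant", random_slope = NULL,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  if (!group %in% names(data)) stop("grouping column '", group, "' not found")
  data[[group]] <- factor(data[[group]])
  if (nlevels(data[[group]]) < 2L)
    stop("singular grouping: need at least 2 levels of '", group, "'")
  resp <- all.vars(formula[[2L]])
  if (anyNA(data[[resp]])) stop("missing values in response '", resp, "'")
  if (!is.null(random_slope) && !random_slope %in% names(data))
    stop("random-slope covariate '", random_slope, "' not found")
  re_term <- if (is.null(random_slope)) "1" else paste("1 +", random_slope)
  rhs <- paste(deparse(formula[[3L]], width.cutoff = 500L), collapse = " ")
  full <- stats::as.formula(
    paste(resp, "~", rhs, "+ (", re_term, "|", group, ")"),
    env = environment(formula))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(full, data = data, REML = (method == "REML")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)[[group]]
  var_u0 <- vc["(Intercept)", "(Intercept)"]
  var_u1 <- if (is.null(random_slope)) 0 else vc[random_slope, random_slope]
  cov_u0u1 <- if (is.null(random_slope)) 0 else vc["(Intercept)", random_slope]
  var_e <- stats::sigma(fit)^2
  eta <- as.vector(lme4::getME(fit, "X") %*% beta)
  n_obs <- length(eta)
  n_params <- length(beta) + 2L + if (is.null(random_slope)) 0L else 2L
  conv_ok <- is.null(fit@optinfo$conv$lme4$code) ||
    fit@optinfo$conv$lme4$code >= 0
  structure(list(
    fit = fit, formula = formula, group = group, random_slope = random_slope,
    method = method, data = data,
    beta = beta, se = se,
    vcomp = c(var_u0 = var_u0, var_u1 = var_u1,
              cov_u0u1 = cov_u0u1, var_e = var_e),
    var_fixed = stats::var(eta),
    slope_x = if (is.null(random_slope)) NULL else data[[random_slope]],
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = n_obs, n_params = n_params,
    converged = conv_ok, singular = lme4::isSingular(fit),
    messages = msgs,
    call = match.call()), class = "amf_mlm")
}

# refit with a different estimation method (identity when already there)
refit_method <- function(object, method) {
  stopifnot(inherits(object, "amf_mlm"))
  if (object$method == method) return(object)
  amf_mlm(object$formula, object$data, group = object$group,
          random_slope = object$random_slope, method = method)
}

#' @export
print.amf_mlm <- function(x, digits = 4, ...) {
  cat("Two-level mixed linear model (", x$method, ")\n", sep = "")
  cat("  fixed:  ", deparse(x$formula), "\n", sep = "")
  cat("  random: (", if (is.null(x$random_slope)) "1" else
    paste("1 +", x$random_slope), " | ", x$group, ")\n", sep = "")
  cat("Fixed effects:\n")
  print(round(x$beta, digits))
  v <- x$vcomp
  cat(sprintf("Variance components: plant %.6g", v["var_u0"]))
  if (!is.null(x$random_slope))
    cat(sprintf(", slope %.6g, covariance %.6g",
                v["var_u1"], v["cov_u0u1"]))
  cat(sprintf(", residual %.6g\n", v["var_e"]))
  if (!x$converged) cat("NOTE: optimizer did not report clean convergence\n")
  invisible(x)
}

#' @export
summary.amf_mlm <- function(object, ...) {
  ct <- cbind(Estimate = object$beta, `Std. Error` = object$se,
              `t value` = object$beta / object$se)
  ic <- information_criteria(object)
  r2 <- r_squared(object)
  structure(list(object = object, coefficients = ct,
                 vcomp = object$vcomp, var_fixed = object$var_fixed,
                 icc = if (is.null(object$random_slope))
                   icc(object) else NA_real_,
                 r_squared = r2, ic = ic,
                 n_obs = object$n_obs, n_groups =
                   nlevels(object$data[[object$group]])),
            class = "summary.amf_mlm")
}

#' @export
print.summary.amf_mlm <- function(x, digits = 4, ...) {
  print(x$object, digits = digits)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nObservations: %d   groups: %d\n", x$n_obs, x$n_groups))
  cat(sprintf("Variance of fixed-effect predictor: %.6g\n", x$var_fixed))
  if (!is.na(x$icc)) cat(sprintf("ICC (plant level): %.4f\n", x$icc))
  cat(sprintf("Marginal R2: %.4f   Conditional R2: %.4f\n",
              x$r_squared[["marginal"]], x$r_squared[["conditional"]]))
  cat(sprintf("AIC: %.4f   BIC: %.4f   Deviance: %.4f\n",
              x$ic[["aic"]], x$ic[["bic"]], x$ic[["deviance"]]))
  invisible(x)
}

#' @export
coef.amf_mlm <- function(object, ...) object$beta

#' @export
logLik.amf_mlm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.amf_mlm <- function(object, ...) object$n_obs

#' @export
predict.amf_mlm <- function(object, newdata = NULL, re.form = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, re.form = re.form, ...)
  else stats::predict(object$fit, newdata = newdata, re.form = re.form,
                      allow.new.levels = TRUE, ...)
}

#' @export
residuals.amf_mlm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
fitted.amf_mlm <- function(object, ...) stats::fitted(object$fit)

#' @export
simulate.amf_mlm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' @export
plot.amf_mlm <- function(x, ...) {
  graphics::plot(fitted(x), residuals(x),
                 xlab = "fitted", ylab = "residual",
                 main = deparse(x$formula), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
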