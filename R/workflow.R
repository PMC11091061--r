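# Inference workflow around the mixed-model engine: lasso screening of
# fixed-effect candidates, greedy forward selection and random-slope
# selection by likelihood ratio tests, the model ladder mirroring the
# null -> region -> covariates -> random-slope sequence, Tukey region
# contrasts and Spearman rank comparison of phenotypes.

#' Lasso screening of candidate fixed effects
#'
#' L1-penalized least squares on the pooled, standardized data, used as a
#' screening step before the mixed-model stage.  The penalty is chosen by
#' seeded k-fold cross-validation with the 1-SE rule; the selected set is
#' the predictors with nonzero coefficients at that penalty.
#'
#' @param X numeric matrix of standardized candidate covariates.
#' @param y response vector.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `selected` (character vector), `lambda` (chosen
#'   penalty), `coefficients` at the chosen penalty, `path` (coefficient
#'   matrix over the penalty grid), `lambda_grid`, and the `cv` object.
#' @export
lasso_screen <- function(X, y, folds = 10, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) > folds, folds >= 2)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2L, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), length(y))))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
                          standardize = FALSE)
  co <- stats::coef(cv, s = "lambda.1se")
  co <- stats::setNames(as.numeric(co), rownames(co))
  co <- co[setdiff(names(co), "(Intercept)")]
  path <- as.matrix(stats::coef(cv$glmnet.fit))
  list(selected = names(co)[co != 0], lambda = cv$lambda.1se,
       coefficients = co, path = path, lambda_grid = cv$lambda, cv = cv,
       seed = seed)
}

#' Greedy forward selection of fixed effects by LRT
#'
#' Starting from a base fixed-effect structure, repeatedly adds the
#' candidate term with the smallest likelihood-ratio p-value (ML fits)
#' while that p-value is below `alpha`.  Deterministic given the data.
#'
#' @param base base fixed-effects formula (e.g. `y ~ region`).
#' @param candidates character vector of candidate terms, disjoint from the
#'   base terms.
#' @param data design table.
#' @param group grouping column (default `"plant"`).
#' @param alpha inclusion threshold (default 0.05).
#' @param random_slope optional random-slope covariate carried through all
#'   fits.
#' @return list with `formula` (final), `selected` (terms added, in
#'   order), `trace` (data.frame of candidate, statistic, df, p, added per
#'   step).
#' @export
forward_select <- function(base, candidates, data, group = "plant",
                           alpha = 0.05, random_slope = NULL) {
  stopifnot(inherits(base, "formula"))
  base_terms <- attr(stats::terms(base), "term.labels")
  if (length(intersect(base_terms, candidates)))
    stop("candidates must be disjoint from the base terms")
  current <- base
  remaining <- candidates
  selected <- character(0)
  trace <- list()
  fit_cur <- amf_mlm(current, data, group = group,
                     random_slope = random_slope, method = "ML")
  while (length(remaining)) {
    ps <- rep(NA_real_, length(remaining))
    stats_ <- ps; dfs <- ps
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      f_try <- stats::update(current, paste(". ~ . +", remaining[k]))
      fits[[k]] <- tryCatch(
        amf_mlm(f_try, data, group = group, random_slope = random_slope,
                method = "ML"),
        error = function(e) NULL)
      if (is.null(fits[[k]])) next
      lrt <- likelihood_ratio_test(fit_cur, fits[[k]])
      ps[k] <- lrt$p; stats_[k] <- lrt$statistic; dfs[k] <- lrt$df
    }
    best <- which.min(ps)
    if (!length(best) || is.na(ps[best])) break
    add <- ps[best] < alpha
    trace[[length(trace) + 1L]] <- data.frame(
      term = remaining[best], statistic = stats_[best], df = dfs[best],
      p = ps[best], added = add, stringsAsFactors = FALSE)
    if (!add) break
    current <- stats::update(current, paste(". ~ . +", remaining[best]))
    fit_cur <- fits[[best]]
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  list(formula = current, selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(term = character(0), statistic = numeric(0),
                    df = integer(0), p = numeric(0), added = logical(0)))
}

#' Select a plant-level random slope by LRT
#'
#' For each candidate covariate, compares the random-intercept model with
#' the model adding a random slope on that covariate (ML fits, 2 df: slope
#' variance and intercept-slope covariance).  At most one slope is
#' retained: the candidate with the smallest p-value below `alpha`.
#'
#' @param formula fixed-effects formula.
#' @param slope_candidates character vector of covariates to test.
#' @param data design table.
#' @param group grouping column.
#' @param alpha retention threshold (default 0.05).
#' @return list with `random_slope` (name or `NULL`) and `table`
#'   (candidate, statistic, df, p).
#' @export
random_slope_search <- function(formula, slope_candidates, data,
                                group = "plant", alpha = 0.05) {
  base <- amf_mlm(formula, data, group = group, method = "ML")
  rows <- list()
  for (cand in slope_candidates) {
    fit <- tryCatch(
      amf_mlm(formula, data, group = group, random_slope = cand,
              method = "ML"),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("random-slope fit for '", cand, "' failed; skipped")
      next
    }
    lrt <- likelihood_ratio_test(base, fit)
    rows[[length(rows) + 1L]] <- data.frame(
      candidate = cand, statistic = lrt$statistic, df = lrt$df, p = lrt$p,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(candidate = character(0), statistic = numeric(0),
               df = integer(0), p = numeric(0))
  keep <- tab$candidate[tab$p < alpha]
  list(random_slope = if (length(keep)) tab$candidate[which.min(tab$p)]
       else NULL, table = tab)
}

#' Build the model ladder
#'
#' Fits the sequence null model; + region; + each selected covariate (in
#' order); + random slope (when given), and tabulates per model the fixed
#' effects, REML variance components, PCV of both levels against the null
#' model, ICC (or the observation-averaged VPC for the slope model),
#' marginal/conditional R-squared, and ML-based AIC/BIC/deviance.
#'
#' @param data design table.
#' @param response response column name.
#' @param covariates character vector of fixed-effect covariates, in the
#'   order they enter the ladder.
#' @param region_var region column name (default `"region"`), entered
#'   right after the null model; `NULL` to skip.
#' @param random_slope covariate given a random slope in the final model,
#'   or `NULL`.
#' @param group grouping column.
#' @return object of class `amf_ladder`: a list with `table` (one row per
#'   model) and `fits` (REML fits).
#' @export
build_model_ladder <- function(data, response, covariates = character(0),
                               region_var = "region", random_slope = NULL,
                               group = "plant") {
  specs <- list(list(label = "null",
                     formula = stats::reformulate("1", response),
                     slope = NULL))
  rhs <- character(0)
  if (!is.null(region_var)) {
    rhs <- region_var
    specs[[length(specs) + 1L]] <-
      list(label = paste0("+", region_var),
           formula = stats::reformulate(rhs, response), slope = NULL)
  }
  for (cv in covariates) {
    rhs <- c(rhs, cv)
    specs[[length(specs) + 1L]] <-
      list(label = paste0("+", cv),
           formula = stats::reformulate(rhs, response), slope = NULL)
  }
  if (!is.null(random_slope))
    specs[[length(specs) + 1L]] <-
      list(label = paste0("+(", random_slope, "|", group, ")"),
           formula = stats::reformulate(rhs, response),
           slope = random_slope)
  fits <- list(); rows <- list()
  null_fit <- NULL
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    fit <- amf_mlm(sp$formula, data, group = group,
                   random_slope = sp$slope, method = "REML")
    fit_ml <- refit_method(fit, "ML")
    if (k == 1L) null_fit <- fit
    ic <- information_criteria(fit_ml)
    r2 <- r_squared(fit)
    has_slope <- !is.null(sp$slope)
    v <- fit$vcomp
    vpc_plant <- if (has_slope) {
      x <- fit$slope_x
      num <- v[["var_u0"]] + v[["var_u1"]] * mean(x^2) +
        2 * v[["cov_u0u1"]] * mean(x)
      num / (num + v[["var_e"]])
    } else icc(fit)
    pcvs <- if (k == 1L) c(plant = NA_real_, sample = NA_real_) else
      pcv_between(null_fit, fit)
    rows[[k]] <- data.frame(
      model = k, label = sp$label,
      n_fixed = length(fit$beta), random_slope = has_slope,
      var_fixed = if (k == 1L) NA_real_ else fit$var_fixed,
      var_plant = v[["var_u0"]], var_slope = v[["var_u1"]],
      cov_intercept_slope = v[["cov_u0u1"]], var_sample = v[["var_e"]],
      pcv_plant = pcvs[["plant"]], pcv_sample = pcvs[["sample"]],
      icc_vpc = vpc_plant,
      r2_marginal = if (k == 1L) NA_real_ else r2[["marginal"]],
      r2_conditional = r2[["conditional"]],
      aic = ic[["aic"]], bic = ic[["bic"]], deviance = ic[["deviance"]],
      converged = fit$converged, stringsAsFactors = FALSE)
    fits[[k]] <- fit
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 response = response), class = "amf_ladder")
}

#' @export
print.amf_ladder <- function(x, digits = 4, ...) {
  cat("Mixed-model ladder for response '", x$response, "'\n", sep = "")
  tb <- x$table
  num <- vapply(tb, is.numeric, TRUE)
  tb[num] <- lapply(tb[num], round, digits = digits)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Write a model-ladder table
#'
#' @param ladder an `amf_ladder` object.
#' @param path output path (tab-delimited).
#' @return the table, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  utils::write.table(ladder$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ladder$table)
}

#' Pairwise region contrasts with Tukey adjustment
#'
#' Pairwise mean differences MID-TOP, MID-BOT, TOP-BOT on the one-way
#' region layout (pooling plants), with p-values from the studentized-range
#' distribution (Tukey) or unadjusted pairwise t-tests.  A plant-blocked
#' variant (region + block two-way layout) is available via `block`.
#'
#' @param values numeric response vector.
#' @param region factor/character with levels TOP, MID, BOT.
#' @param adjust `"tukey"` (default) or `"none"`.
#' @param block optional blocking factor (e.g. plant) removed from the
#'   error term.
#' @return data.frame with `contrast`, `estimate`, `p`.
#' @export
region_contrasts <- function(values, region, adjust = c("tukey", "none"),
                             block = NULL) {
  adjust <- match.arg(adjust)
  region <- factor(as.character(region), levels = c("TOP", "MID", "BOT"))
  if (anyNA(region)) stop("region must only contain TOP, MID, BOT")
  cnt <- table(region)
  if (any(cnt < 2L)) stop("every region needs at least 2 observations")
  if (is.null(block)) {
    fitaov <- stats::aov(values ~ region)
  } else {
    block <- factor(block)
    fitaov <- stats::aov(values ~ region + block)
  }
  an <- stats::anova(fitaov)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  means <- tapply(values, region, mean)
  pairs <- list(c("MID", "TOP"), c("MID", "BOT"), c("TOP", "BOT"))
  out <- lapply(pairs, function(pr) {
    est <- means[[pr[1L]]] - means[[pr[2L]]]
    sed <- sqrt(mse * (1 / cnt[[pr[1L]]] + 1 / cnt[[pr[2L]]]))
    p <- if (adjust == "tukey")
      stats::ptukey(abs(est) / (sed / sqrt(2)), nmeans = nlevels(region),
                    df = dfe, lower.tail = FALSE)
    else 2 * stats::pt(abs(est) / sed, df = dfe, lower.tail = FALSE)
    data.frame(contrast = paste(pr, collapse = "-"), estimate = est, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Spearman rank comparison of two phenotypes
#'
#' Spearman rank correlation (midranks for ties) with the t-approximation
#' p-value, used to compare how two colonization phenotypes rank the
#' plants.
#'
#' @param a,b paired numeric vectors (length >= 4).
#' @return list with `rho` and `p`.
#' @export
rank_compare <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 4L) stop("need at least 4 paired observations")
  ra <- rank(a); rb <- rank(b)
  rho <- stats::cor(ra, rb)
  tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}
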