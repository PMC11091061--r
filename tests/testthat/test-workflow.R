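test_that("lasso reduces to OLS at zero penalty and to zero at large penalty", {
  set.seed(5)
  n <- 80
  X <- scale(matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("v", 1:4)
  y <- drop(X %*% c(1, 0.5, 0, 0)) + rnorm(n, sd = 0.3)
  fit <- glmnet::glmnet(X, y, alpha = 1, standardize = FALSE,
                        lambda = c(1e3, 0))
  ols <- coef(lm(y ~ X))
  expect_equal(unname(as.numeric(coef(fit, s = 0))[-1]), unname(ols[-1]),
               tolerance = 1e-3)
  expect_equal(unname(as.numeric(coef(fit, s = 1e3))[-1]), rep(0, 4))
})

test_that("lasso screening matches soft-thresholded OLS on orthonormal designs", {
  set.seed(6)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)  # X'X = n I
  colnames(Q) <- c("a", "b", "c")
  beta <- c(0.9, -0.4, 0)
  y <- drop(Q %*% beta) + rnorm(n, sd = 0.2)
  b_ols <- drop(crossprod(Q, y)) / n
  lam <- 0.2
  soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
  fit <- glmnet::glmnet(Q, y, alpha = 1, standardize = FALSE,
                        intercept = FALSE, lambda = lam, thresh = 1e-12)
  expect_equal(unname(as.numeric(coef(fit))[-1]), unname(soft),
               tolerance = 1e-4)
})

test_that("lasso screening is seeded-reproducible and drops constants", {
  d <- simulate_mlm_dataset(sim_mlm_params(I = 12), seed = 11)
  X <- cbind(as.matrix(d[, c("arb_count_scaled", "arb_size_scaled")]),
             flat = 1)
  expect_warning(s1 <- lasso_screen(X, d$y, seed = 42), "constant")
  expect_warning(s2 <- lasso_screen(X, d$y, seed = 42), "constant")
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$lambda, s2$lambda)
  # the two simulated true effects are screened in
  expect_setequal(s1$selected, c("arb_count_scaled", "arb_size_scaled"))
})

test_that("forward selection adds strong terms and stops on null ones", {
  d <- simulate_mlm_dataset(sim_mlm_params(I = 12), seed = 19)
  fs <- forward_select(y ~ region, c("arb_count_scaled", "arb_size_scaled"),
                       d)
  expect_equal(fs$selected[1], "arb_count_scaled")  # largest true effect first
  expect_setequal(fs$selected, c("arb_count_scaled", "arb_size_scaled"))
  # empty candidate list returns the base unchanged
  fs0 <- forward_select(y ~ region, character(0), d)
  expect_equal(deparse(fs0$formula), "y ~ region")
  expect_equal(nrow(fs0$trace), 0)
  # pure-noise candidates are mostly rejected (>= 90% of seeded reps)
  null_rejections <- 0L
  for (s in 1:20) {
    dn <- simulate_mlm_dataset(
      sim_mlm_params(I = 48, beta_count = 0, beta_size = 0, var_u1 = 0),
      seed = 100 + s)
    fsn <- forward_select(y ~ region,
                          c("arb_count_scaled", "arb_size_scaled"), dn)
    if (length(fsn$selected) == 0) null_rejections <- null_rejections + 1L
  }
  expect_gte(null_rejections, 18L)
})

test_that("random-slope search keeps a real slope and skips absent ones", {
  d <- simulate_mlm_dataset(
    sim_mlm_params(I = 24, var_u1 = 4e-3, cov_u0u1 = 0), seed = 27)
  rs <- random_slope_search(y ~ region + arb_count_scaled + arb_size_scaled,
                            c("arb_count_scaled", "arb_size_scaled"), d)
  expect_equal(rs$random_slope, "arb_count_scaled")
  # empty candidate list: nothing retained
  rs0 <- random_slope_search(y ~ region, character(0), d)
  expect_null(rs0$random_slope)
  # no simulated slope: mostly nothing retained
  none <- 0L
  for (s in 1:10) {
    dn <- simulate_mlm_dataset(sim_mlm_params(I = 12, var_u1 = 0),
                               seed = 200 + s)
    rsn <- random_slope_search(y ~ region + arb_count_scaled,
                               "arb_count_scaled", dn)
    if (is.null(rsn$random_slope)) none <- none + 1L
  }
  expect_gte(none, 8L)
})

test_that("the model ladder mirrors the null -> slope sequence", {
  d <- simulate_mlm_dataset(sim_mlm_params(I = 24), seed = 33)
  lad <- build_model_ladder(d, "y",
                            covariates = c("arb_count_scaled",
                                           "arb_size_scaled"),
                            random_slope = "arb_count_scaled")
  tb <- lad$table
  expect_equal(nrow(tb), 5)
  # null row: no PCV (reference), no marginal R2, ICC = conditional R2
  expect_true(is.na(tb$pcv_plant[1]) && is.na(tb$r2_marginal[1]))
  expect_equal(tb$icc_vpc[1], tb$r2_conditional[1], tolerance = 1e-10)
  # ML deviance is non-increasing down the nested ladder
  expect_true(all(diff(tb$deviance) <= 1e-6))
  expect_true(all(tb$converged))
  # writing round-trips
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ladder(lad, path)
  back <- read.delim(path)
  expect_equal(back$deviance, tb$deviance, tolerance = 1e-6)
})

test_that("ladder PCVs stay near zero when no fixed effects are simulated", {
  pcvs <- numeric(20)
  for (s in seq_along(pcvs)) {
    d <- simulate_mlm_dataset(
      sim_mlm_params(I = 96, beta_top = 0, beta_bot = 0, beta_count = 0,
                     beta_size = 0, var_u1 = 0), seed = 300 + s)
    lad <- build_model_ladder(d, "y", covariates = "arb_count_scaled")
    pcvs[s] <- lad$table$pcv_plant[3]
  }
  expect_lt(median(abs(pcvs)), 0.1)
})

test_that("region contrasts match TukeyHSD and pairwise t oracles", {
  set.seed(44)
  reg <- rep(c("TOP", "MID", "BOT"), each = 12)
  y <- rnorm(36) + 0.8 * (reg == "TOP")
  ct <- region_contrasts(y, reg, adjust = "tukey")
  expect_equal(ct$contrast, c("MID-TOP", "MID-BOT", "TOP-BOT"))
  hsd <- TukeyHSD(aov(y ~ factor(reg, levels = c("TOP", "MID", "BOT"))))[[1]]
  expect_equal(ct$estimate[ct$contrast == "MID-TOP"],
               unname(hsd["MID-TOP", "diff"]), tolerance = 1e-10)
  expect_equal(ct$p[ct$contrast == "MID-TOP"],
               unname(hsd["MID-TOP", "p adj"]), tolerance = 1e-8)
  expect_equal(ct$p[ct$contrast == "TOP-BOT"],
               unname(hsd[rownames(hsd) %in% c("BOT-TOP", "TOP-BOT"),
                          "p adj"]), tolerance = 1e-8)
  # unadjusted equals the pooled-variance pairwise t-test
  cn <- region_contrasts(y, reg, adjust = "none")
  ptt <- pairwise.t.test(y, reg, p.adjust.method = "none")$p.value
  expect_equal(cn$p[cn$contrast == "MID-TOP"], ptt["TOP", "MID"],
               tolerance = 1e-10)
  # Tukey-adjusted p is never smaller than unadjusted
  expect_true(all(ct$p >= cn$p - 1e-12))
})

test_that("region contrasts detect a large shift and handle ties", {
  set.seed(45)
  reg <- rep(c("TOP", "MID", "BOT"), each = 10)
  y <- rnorm(30, sd = 1) + 5 * (reg == "TOP")
  ct <- region_contrasts(y, reg)
  expect_lt(ct$p[ct$contrast == "TOP-BOT"], 0.001)
  y0 <- rep(1:10, 3)
  ct0 <- region_contrasts(y0, reg)
  expect_equal(ct0$estimate, rep(0, 3))
  expect_error(region_contrasts(y[1:4], c("TOP", "MID", "BOT", "BOT")),
               "at least 2")
})

test_that("blocked region contrasts remove the plant stratum", {
  set.seed(46)
  plant <- rep(1:8, each = 3)
  reg <- rep(c("TOP", "MID", "BOT"), 8)
  y <- rnorm(24, sd = 0.2) + rep(rnorm(8, sd = 2), each = 3) +
    1 * (reg == "TOP")
  pooled <- region_contrasts(y, reg)
  blocked <- region_contrasts(y, reg, block = plant)
  # blocking strips the large plant variance, sharpening the contrast
  expect_lt(blocked$p[blocked$contrast == "TOP-BOT"],
            pooled$p[pooled$contrast == "TOP-BOT"])
})

test_that("rank comparison is midrank Spearman with the t approximation", {
  expect_equal(rank_compare(1:10, 2 * (1:10))$rho, 1)
  expect_equal(rank_compare(1:10, rev(1:10))$rho, -1)
  set.seed(47)
  a <- rnorm(30); b <- a + rnorm(30)
  b[3] <- b[5]  # introduce a tie
  rc <- rank_compare(a, b)
  rho <- cor(rank(a), rank(b))
  expect_equal(rc$rho, rho, tolerance = 1e-10)
  tt <- rho * sqrt(28 / (1 - rho^2))
  expect_equal(rc$p, 2 * pt(-abs(tt), 28), tolerance = 1e-10)
  expect_error(rank_compare(1:3, 3:1), "at least 4")
})
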