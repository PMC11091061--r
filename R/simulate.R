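# Seeded synthetic-data generators with the statistical structure the
# analysis assumes: the two-level generative model behind the ladder, slide
# instance tables with correlated class counts, and mask pairs with known
# matching bookkeeping for the evaluation metrics.  Every generator is a
# pure function of its parameters and seed.

#' Parameters of the two-level generative model
#'
#' Defaults reproduce the study conditions of the motivating sorghum RIL
#' experiment: 12 plants, 3 root regions (TOP/MID/BOT), 3 replicates per
#' region, and the random-intercept + random-slope model for percent
#' colonization (intercept 0.3410, regionTOP 0.0226, regionBOT -0.0087,
#' scaled arbuscule count 0.0937, scaled arbuscule size 0.0304; intercept
#' variance 9e-4, residual variance 7e-4).  The slope variance default
#' (4e-4) is synthetic-only: it is set so the plant-level variance visibly
#' grows with arbuscule count; no published estimate exists for it.
#'
#' @param I number of plants (>= 2).
#' @param J replicates per region (default 3).
#' @param beta0,beta_top,beta_bot fixed intercept and region effects
#'   (reference level MID).
#' @param beta_count,beta_size fixed effects of the scaled arbuscule count
#'   and size covariates.
#' @param var_u0,var_u1,cov_u0u1,var_e variance components.
#' @param seed not stored here; pass to [simulate_mlm_dataset()].
#' @return list of class `sim_mlm_params`.
#' @export
sim_mlm_params <- function(I = 12L, J = 3L,
                           beta0 = 0.3410, beta_top = 0.0226,
                           beta_bot = -0.0087, beta_count = 0.0937,
                           beta_size = 0.0304,
                           var_u0 = 9e-4, var_u1 = 4e-4, cov_u0u1 = 0,
                           var_e = 7e-4) {
  stopifnot(I >= 2, J >= 1, var_u0 >= 0, var_u1 >= 0, var_e >= 0)
  if (cov_u0u1^2 > var_u0 * var_u1 * (1 + 1e-12))
    stop("invalid covariance: random-effect matrix not positive semi-definite")
  structure(list(I = as.integer(I), J = as.integer(J), beta0 = beta0,
                 beta_top = beta_top, beta_bot = beta_bot,
                 beta_count = beta_count, beta_size = beta_size,
                 var_u0 = var_u0, var_u1 = var_u1, cov_u0u1 = cov_u0u1,
                 var_e = var_e), class = "sim_mlm_params")
}

#' Simulate a hierarchical design table
#'
#' Draws plant-level random intercepts and slopes jointly normal,
#' independent sample-level errors, standard-normal scaled covariates, and
#' assembles the response per the random-intercept + random-slope model
#' (the slope acts on the scaled arbuscule count).  The latent truths are
#' attached for parameter-recovery tests.
#'
#' @param params a [sim_mlm_params()] object.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with columns `plant`, `region`, `replicate`,
#'   `arb_count_scaled`, `arb_size_scaled`, `y`; attributes `params`,
#'   `u0`, `u1` carry the generator truth.
#' @export
simulate_mlm_dataset <- function(params = sim_mlm_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_mlm_params"))
  p <- params
  regions <- c("TOP", "MID", "BOT")
  n <- p$I * 3L * p$J
  with_seed(seed, {
    # joint normal (u0, u1): u1 | u0 conditional draw via Cholesky
    S <- matrix(c(p$var_u0, p$cov_u0u1, p$cov_u0u1, p$var_u1), 2L)
    L <- chol_psd(S)
    Z <- matrix(stats::rnorm(2L * p$I), ncol = 2L)
    U <- Z %*% t(L)
    d <- data.frame(
      plant = factor(rep(sprintf("P%02d", seq_len(p$I)), each = 3L * p$J)),
      region = factor(rep(rep(regions, each = p$J), times = p$I),
                      levels = c("MID", "TOP", "BOT")),
      replicate = rep(seq_len(p$J), times = 3L * p$I))
    d$arb_count_scaled <- stats::rnorm(n)
    d$arb_size_scaled <- stats::rnorm(n)
    i <- as.integer(d$plant)
    eta <- p$beta0 + p$beta_top * (d$region == "TOP") +
      p$beta_bot * (d$region == "BOT") +
      p$beta_count * d$arb_count_scaled + p$beta_size * d$arb_size_scaled
    d$y <- as.numeric(eta + U[i, 1L] + U[i, 2L] * d$arb_count_scaled +
                        stats::rnorm(n, sd = sqrt(p$var_e)))
    attr(d, "params") <- p
    attr(d, "u0") <- U[, 1L]
    attr(d, "u1") <- U[, 2L]
    d
  })
}

# Cholesky-like factor tolerant of semi-definite matrices
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10) stop("invalid covariance matrix")
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*% t(ev$vectors)
}

#' Parameters of the slide instance-table generator
#'
#' Per-slide class counts follow a Gaussian copula over Poisson margins so
#' the sign structure of the observed count correlations can be set
#' directly: arbuscule and extraradical-hypha counts positively correlated,
#' vesicle and spore counts positively correlated, and vesicle/spore counts
#' negatively correlated with a latent arbuscule-size factor.  Instance
#' pixel areas are log-normal per class; each slide carries one root
#' instance consuming the root pixel budget; confidences are Beta-drawn per
#' class (left-skewed).  Region effects multiply arbuscule and
#' extraradical-hypha intensities and shift arbuscule size so TOP > MID >
#' BOT.  The per-class magnitudes are order-of-magnitude choices, not
#' estimates of any real dataset.
#'
#' @param mean_counts named mean counts per slide for the five AMF classes.
#' @param size_meanlog,size_sdlog log-normal location/scale of instance
#'   pixel areas per class.
#' @param root_pixels root pixel budget per slide.
#' @param rho_arb_exh,rho_ves_sp,rho_size_vs correlation targets of the
#'   latent Gaussian copula.
#' @param region_count_mult multiplicative region effect on arb/exH counts
#'   (TOP, MID, BOT).
#' @param region_size_shift additive region shift on the arbuscule
#'   `meanlog` (TOP, MID, BOT).
#' @param conf_shape1,conf_shape2 Beta parameters of structure confidences.
#' @param plant_count_sd,plant_size_sd standard deviations of the
#'   plant-level random effects on the log count intensities and on the
#'   arbuscule size `meanlog`; these create the between-plant clustering
#'   (nonzero ICC) that the hierarchical models partition.
#' @return list of class `sim_instance_params`.
#' @export
sim_instance_params <- function(
    mean_counts = c(arb = 8, exH = 5, inH = 4, ves = 4, sp = 3),
    size_meanlog = c(arb = log(150), exH = log(400), inH = log(300),
                     ves = log(250), sp = log(350)),
    size_sdlog = c(arb = 0.4, exH = 0.5, inH = 0.5, ves = 0.35, sp = 0.35),
    root_pixels = 2e4,
    rho_arb_exh = 0.5, rho_ves_sp = 0.4, rho_size_vs = -0.35,
    region_count_mult = c(TOP = 1.4, MID = 1.0, BOT = 0.7),
    region_size_shift = c(TOP = 0.25, MID = 0, BOT = -0.25),
    conf_shape1 = 6, conf_shape2 = 2,
    plant_count_sd = 0.35, plant_size_sd = 0.15) {
  stopifnot(all(mean_counts >= 0), root_pixels > 0,
            abs(rho_arb_exh) < 1, abs(rho_ves_sp) < 1, abs(rho_size_vs) < 1)
  cls <- c("arb", "exH", "inH", "ves", "sp")
  R <- diag(6L)  # latent order: five counts + arbuscule size factor
  dimnames(R) <- list(c(cls, "arb_size"), c(cls, "arb_size"))
  R["arb", "exH"] <- R["exH", "arb"] <- rho_arb_exh
  R["ves", "sp"] <- R["sp", "ves"] <- rho_ves_sp
  R["ves", "arb_size"] <- R["arb_size", "ves"] <- rho_size_vs
  R["sp", "arb_size"] <- R["arb_size", "sp"] <- rho_size_vs
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8)
    stop("infeasible correlation targets (latent matrix not positive ",
         "definite); reduce the magnitudes, e.g. scale them by ",
         sprintf("%.2f", sqrt(max(0, 1 + ev))))
  structure(list(mean_counts = mean_counts, size_meanlog = size_meanlog,
                 size_sdlog = size_sdlog, root_pixels = root_pixels,
                 latent_corr = R,
                 region_count_mult = region_count_mult,
                 region_size_shift = region_size_shift,
                 conf_shape1 = conf_shape1, conf_shape2 = conf_shape2,
                 plant_count_sd = plant_count_sd,
                 plant_size_sd = plant_size_sd),
            class = "sim_instance_params")
}

#' Simulate per-slide instance records
#'
#' Generates one instance table per slide of a design (one row per
#' segmented object): a single root instance with the root pixel budget,
#' then per AMF class a copula-correlated Poisson count of instances with
#' log-normal pixel areas and Beta confidences.
#'
#' @param params a [sim_instance_params()] object.
#' @param design data.frame with columns `plant`, `region`, `replicate`
#'   (e.g. from [simulate_mlm_dataset()], one slide per row) or a
#'   `slide_id` + `region` pair.
#' @param seed integer seed.
#' @return data.frame of instance records: `slide_id`, `image_id`,
#'   `class_label`, `pixel_area`, `confidence`.
#' @export
simulate_instance_tables <- function(params = sim_instance_params(),
                                     design, seed = 1L) {
  stopifnot(inherits(params, "sim_instance_params"))
  if (!"slide_id" %in% names(design)) {
    stopifnot(all(c("plant", "region", "replicate") %in% names(design)))
    design$slide_id <- sprintf("%s_%s_%d", design$plant, design$region,
                               design$replicate)
  }
  cls <- c("arb", "exH", "inH", "ves", "sp")
  L <- chol_psd(params$latent_corr)
  with_seed(seed, {
    # plant-level random effects induce the between-plant clustering the
    # mixed models partition; without a plant column slides are independent
    if ("plant" %in% names(design)) {
      plants <- unique(as.character(design$plant))
      b_count <- stats::setNames(
        stats::rnorm(length(plants), 0, params$plant_count_sd), plants)
      b_size <- stats::setNames(
        stats::rnorm(length(plants), 0, params$plant_size_sd), plants)
    } else b_count <- b_size <- NULL
    rows <- vector("list", nrow(design))
    for (s in seq_len(nrow(design))) {
      reg <- as.character(design$region[s])
      lam <- params$mean_counts
      mult <- params$region_count_mult[[reg]]
      lam[c("arb", "exH")] <- lam[c("arb", "exH")] * mult
      if (!is.null(b_count)) {
        pl <- as.character(design$plant[s])
        lam <- lam * exp(b_count[[pl]])
      }
      z <- as.vector(L %*% stats::rnorm(6L))
      names(z) <- colnames(params$latent_corr)
      counts <- stats::qpois(stats::pnorm(z[cls]), lambda = lam[cls])
      rec <- list(data.frame(
        slide_id = design$slide_id[s], image_id = paste0(design$slide_id[s], "_img1"),
        class_label = "root", pixel_area = params$root_pixels,
        confidence = stats::rbeta(1L, 30, 1.5), stringsAsFactors = FALSE))
      for (cl in cls) {
        k <- counts[[cl]]
        if (k == 0L) next
        ml <- params$size_meanlog[[cl]]
        if (cl == "arb") {
          ml <- ml + params$region_size_shift[[reg]] + 0.3 * z[["arb_size"]]
          if (!is.null(b_size))
            ml <- ml + b_size[[as.character(design$plant[s])]]
        }
        sizes <- pmax(1, round(stats::rlnorm(k, ml, params$size_sdlog[[cl]])))
        rec[[length(rec) + 1L]] <- data.frame(
          slide_id = design$slide_id[s],
          image_id = paste0(design$slide_id[s], "_img1"),
          class_label = cl, pixel_area = sizes,
          confidence = stats::rbeta(k, params$conf_shape1, params$conf_shape2),
          stringsAsFactors = FALSE)
      }
      rows[[s]] <- do.call(rbind, rec)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate matched truth/prediction mask pairs
#'
#' Places non-overlapping geometric truth masks (rectangles, ellipses and
#' thin filaments emulating hyphae) on a raster with margins wider than the
#' jitter, then builds predictions as jittered copies (random translation
#' up to `jitter` pixels), drops each with probability `drop_rate`, and
#' adds spurious predictions disjoint from every truth with rate
#' `spurious_rate`.  Because truths are separated by more than twice the
#' jitter, each prediction can only overlap its source truth, so the
#' returned bookkeeping (per-prediction source and IoU) determines TP/FP/FN
#' exactly at any threshold.
#'
#' @param n number of truth instances (>= 1).
#' @param jitter maximum translation of a predicted mask, pixels.
#' @param drop_rate probability a truth has no prediction.
#' @param spurious_rate expected number of spurious predictions per truth.
#' @param classes class labels cycled over the instances.
#' @param seed integer seed.
#' @return list with `truths`, `preds` (lists of [mask_instance()]),
#'   and `bookkeeping`: data.frame with one row per prediction
#'   (`source` truth index or `NA` for spurious, `iou` with the source).
#' @export
simulate_mask_pairs <- function(n, jitter = 1, drop_rate = 0.1,
                                spurious_rate = 0.1,
                                classes = c("arb", "ves", "sp", "exH"),
                                seed = 1L) {
  stopifnot(n >= 1)
  cell <- 48L
  margin <- ceiling(2 * jitter) + 8L
  ncol_grid <- ceiling(sqrt(2 * n))  # room for spurious shapes too
  width <- ncol_grid * cell + margin
  pix_id <- function(xs, ys) as.integer(xs + ys * width)
  shape_pixels <- function(kind, cx, cy) {
    if (kind == 1L) {            # rectangle
      g <- expand.grid(x = (cx - 8):(cx + 8), y = (cy - 6):(cy + 6))
    } else if (kind == 2L) {     # ellipse
      g <- expand.grid(x = (cx - 10):(cx + 10), y = (cy - 7):(cy + 7))
      g <- g[((g$x - cx) / 10)^2 + ((g$y - cy) / 7)^2 <= 1, ]
    } else {                     # thin diagonal filament
      t <- 0:28
      g <- unique(rbind(data.frame(x = cx - 14 + t, y = cy - 7 + floor(t / 2)),
                        data.frame(x = cx - 14 + t, y = cy - 6 + floor(t / 2))))
    }
    pix_id(g$x, g$y)
  }
  with_seed(seed, {
    truths <- vector("list", n)
    slots <- sample(seq_len(ncol_grid^2), n)
    centers <- cbind(((slots - 1L) %% ncol_grid) * cell + cell %/% 2 + margin %/% 2,
                     ((slots - 1L) %/% ncol_grid) * cell + cell %/% 2 + margin %/% 2)
    kinds <- sample(1:3, n, replace = TRUE)
    for (i in seq_len(n))
      truths[[i]] <- mask_instance("sim", classes[(i - 1L) %% length(classes) + 1L],
                                   shape_pixels(kinds[i], centers[i, 1L],
                                                centers[i, 2L]), 1)
    preds <- list(); book <- list()
    for (i in seq_len(n)) {
      if (stats::runif(1) < drop_rate) next
      dx <- sample(-ceiling(jitter):ceiling(jitter), 1L)
      dy <- sample(-ceiling(jitter):ceiling(jitter), 1L)
      px <- pix_id((truths[[i]]$pixels %% width) + dx,
                   (truths[[i]]$pixels %/% width) + dy)
      pm <- mask_instance("sim", truths[[i]]$class_label, px,
                          stats::runif(1, 0.55, 0.99))
      preds[[length(preds) + 1L]] <- pm
      book[[length(book) + 1L]] <- data.frame(
        source = i, iou = mask_iou(pm, truths[[i]]))
    }
    n_spur <- stats::rpois(1L, spurious_rate * n)
    if (n_spur > 0L) {
      free <- setdiff(seq_len(ncol_grid^2), slots)
      n_spur <- min(n_spur, length(free))
      sp_slots <- if (n_spur) sample(free, n_spur) else integer(0)
      for (ssl in sp_slots) {
        cx <- ((ssl - 1L) %% ncol_grid) * cell + cell %/% 2 + margin %/% 2
        cy <- ((ssl - 1L) %/% ncol_grid) * cell + cell %/% 2 + margin %/% 2
        pm <- mask_instance("sim", sample(classes, 1L),
                            shape_pixels(sample(1:3, 1L), cx, cy),
                            stats::runif(1, 0.55, 0.99))
        preds[[length(preds) + 1L]] <- pm
        book[[length(book) + 1L]] <- data.frame(source = NA_integer_, iou = 0)
      }
    }
    list(truths = truths, preds = preds,
         bookkeeping = if (length(book)) do.call(rbind, book) else
           data.frame(source = integer(0), iou = numeric(0)))
  })
}
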