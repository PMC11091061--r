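# Independent oracles and fixture builders shared across the suite.

# even-odd point-in-polygon (crossing test), used as the brute-force
# rasterization oracle; boundary points are measure zero for the random
# polygons used and are avoided by non-integer vertices
pip_even_odd <- function(P, px, py) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  inside <- FALSE
  for (k in seq_len(n)) {
    if ((P[k, 2L] > py) != (P[j[k], 2L] > py)) {
      xc <- P[k, 1L] + (py - P[k, 2L]) / (P[j[k], 2L] - P[k, 2L]) *
        (P[j[k], 1L] - P[k, 1L])
      if (px < xc) inside <- !inside
    }
  }
  inside
}

brute_force_raster <- function(P, width, height) {
  ids <- integer(0)
  for (y in seq_len(height) - 1L)
    for (x in seq_len(width) - 1L)
      if (pip_even_odd(P, x + 0.5, y + 0.5)) ids <- c(ids, x + y * width)
  as.integer(ids)
}

# random simple polygon: points around a center sorted by angle (star-shaped)
random_simple_polygon <- function(n = 8L, cx = 30, cy = 30, rmax = 25) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmax / 4, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# random in-frame simple shapes: clamp to the frame and dissect, as the
# annotation parser does (clamping can introduce self-intersections)
random_frame_shapes <- function(n_shapes, width, height, class_label = "arb") {
  out <- list()
  for (i in seq_len(n_shapes)) {
    V <- random_simple_polygon(sample(4:9, 1),
                               cx = stats::runif(1, 5, width - 5),
                               cy = stats::runif(1, 5, height - 5),
                               rmax = stats::runif(1, 5, 50))
    V[, 1] <- pmin(pmax(V[, 1], 0), width)
    V[, 2] <- pmin(pmax(V[, 2], 0), height)
    out <- c(out, repair_polygon(polygon_shape(V, class_label)))
  }
  out
}

# balanced one-way design for the ANOVA oracle
balanced_oneway <- function(I, J, var_u, var_e) {
  d <- data.frame(plant = factor(rep(seq_len(I), each = J)))
  d$y <- rep(stats::rnorm(I, 0, sqrt(var_u)), each = J) +
    stats::rnorm(I * J, 0, sqrt(var_e))
  d
}

# closed-form REML/ANOVA estimator on the balanced one-way layout; at the
# boundary (MSB < MSW) the constrained REML solution collapses to the iid
# model, whose REML residual variance is SS_tot / (n - 1), not MSW
anova_oneway_components <- function(d, J) {
  a <- stats::anova(stats::aov(y ~ plant, d))
  msb <- a["plant", "Mean Sq"]; msw <- a["Residuals", "Mean Sq"]
  if (msb >= msw) c(var_u = (msb - msw) / J, var_e = msw)
  else c(var_u = 0,
         var_e = sum((d$y - mean(d$y))^2) / (nrow(d) - 1))
}

# simulated design joined with its instance-derived phenotypes
simulated_phenotypes <- function(seed_design = 1L, seed_inst = 2L, I = 12L) {
  d <- simulate_mlm_dataset(sim_mlm_params(I = I), seed = seed_design)
  d$slide_id <- sprintf("%s_%s_%d", d$plant, d$region, d$replicate)
  recs <- simulate_instance_tables(design = d, seed = seed_inst)
  merge(aggregate_slides(recs),
        d[, c("slide_id", "plant", "region", "replicate")], by = "slide_id")
}

# brute-force AP at one threshold: enumerate PR points over the
# confidence-sorted predictions, 101-point interpolation
brute_force_ap <- function(ious, n_truth, threshold) {
  # ious: per prediction (confidence-sorted) IoU with its own truth; each
  # prediction overlaps at most one truth
  tp <- ious >= threshold
  # one-to-one: a truth can be claimed once
  seen <- logical(n_truth)
  src <- attr(ious, "source")
  for (i in which(tp)) {
    if (seen[src[i]]) tp[i] <- FALSE else seen[src[i]] <- TRUE
  }
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / n_truth; prec <- ctp / (ctp + cfp)
  ap <- 0
  for (r in seq(0, 1, 0.01)) {
    ok <- rec >= r - 1e-12
    ap <- ap + if (any(ok)) max(prec[which(ok)[1]:length(prec)]) else 0
  }
  100 * ap / 101
}
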