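# Slide-level colonization phenotypes from instance-segmentation records.
#
# An instance record is one segmented object in one image: slide id, image
# id, canonical class label, pixel area and classifier confidence.  Per
# slide and AMF class three statistics are derived:
#   count density        = instance count / root pixels   (count/pixel)
#   average class size   = class pixels   / instance count (pixel/count)
#   percent colonization = class pixels   / root pixels    (pixel/pixel)
# plus the derived proportion of nutrient-exchange structures (PNE).

#' Aggregate instance records into slide phenotypes
#'
#' Filters records below the confidence threshold, accumulates per-class
#' counts and pixel sums per slide (root pixels sum over all root instances
#' across the slide's images), and derives the class-level statistics,
#' AMF totals and PNE.  Average size is `NA` for classes with zero
#' instances.
#'
#' @param records data.frame with columns `slide_id`, `class_label`,
#'   `pixel_area`, `confidence` (and optionally `image_id`).
#' @param conf_threshold minimum confidence retained (default 0.7).
#' @param amf_classes classes counted in the AMF totals; defaults to the
#'   five AMF structures (the `other` class never enters totals).
#' @param pne_classes classes counted as nutrient-exchange structures in
#'   the PNE numerator (default arbuscules + extraradical hyphae).
#' @return data.frame with one row per slide: `count_<c>`, `pixels_<c>`,
#'   `count_density_<c>`, `avg_size_<c>`, `pct_colonization_<c>` for each
#'   AMF class, `root_pixels`, `total_pct_colonization`,
#'   `total_count_density` and `pne`.
#' @export
aggregate_slides <- function(records, conf_threshold = 0.7,
                             amf_classes = c("arb", "exH", "inH", "ves", "sp"),
                             pne_classes = c("arb", "exH")) {
  need <- c("slide_id", "class_label", "pixel_area", "confidence")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!nrow(records)) stop("empty record list")
  if (any(records$pixel_area < 1)) stop("pixel_area must be >= 1")
  stopifnot(all(pne_classes %in% amf_classes))
  rec <- records[records$confidence >= conf_threshold, , drop = FALSE]
  slides <- unique(records$slide_id)
  rows <- vector("list", length(slides))
  for (si in seq_along(slides)) {
    sl <- rec[rec$slide_id == slides[si], , drop = FALSE]
    root_px <- sum(sl$pixel_area[sl$class_label == "root"])
    if (root_px <= 0)
      stop("slide '", slides[si],
           "' has zero root pixels after filtering; phenotypes undefined")
    row <- list(slide_id = slides[si], root_pixels = root_px)
    for (cl in amf_classes) {
      m <- sl$class_label == cl
      cnt <- sum(m); px <- sum(sl$pixel_area[m])
      row[[paste0("count_", cl)]] <- cnt
      row[[paste0("pixels_", cl)]] <- px
      row[[paste0("count_density_", cl)]] <- cnt / root_px
      row[[paste0("avg_size_", cl)]] <- if (cnt > 0) px / cnt else NA_real_
      row[[paste0("pct_colonization_", cl)]] <- px / root_px
    }
    row$total_pct_colonization <-
      sum(unlist(row[paste0("pct_colonization_", amf_classes)]))
    row$total_count_density <-
      sum(unlist(row[paste0("count_density_", amf_classes)]))
    cnts <- unlist(row[paste0("count_", amf_classes)])
    names(cnts) <- amf_classes
    row$pne <- proportion_nutrient_exchange(cnts, pne_classes)
    rows[[si]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of nutrient-exchange structures (PNE)
#'
#' Count of arbuscules plus extraradical hyphae divided by the count of all
#' AMF structures on the slide; a count-based measure of allocation to the
#' structures mediating nutrient exchange.
#'
#' @param counts named vector of per-class instance counts (AMF classes).
#' @param pne_classes names of the nutrient-exchange classes.
#' @return proportion in `[0, 1]`, or `NA` when the total AMF count is zero.
#' @export
proportion_nutrient_exchange <- function(counts,
                                         pne_classes = c("arb", "exH")) {
  total <- sum(counts)
  if (total <= 0) {
    warning("zero total AMF count; PNE undefined")
    return(NA_real_)
  }
  sum(counts[names(counts) %in% pne_classes]) / total
}

#' Transform proportion-valued phenotypes
#'
#' `logit(p) = log((p + eps) / (1 - p + eps))`;
#' `arcsine_sqrt(p) = asin(sqrt(p))`.  With the default `eps = 0` callers
#' must pre-clip exact 0/1 values for the logit.
#'
#' @param values numeric vector in `[0, 1]` (for the non-identity kinds).
#' @param kind one of `"identity"`, `"logit"`, `"arcsine_sqrt"`.
#' @param eps offset added inside the logit (default 0).
#' @return transformed vector, same length and order.
#' @export
phenotype_transform <- function(values,
                                kind = c("identity", "logit", "arcsine_sqrt"),
                                eps = 0) {
  kind <- match.arg(kind)
  if (kind == "identity") return(values)
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad))
    stop("values outside [0, 1] at index ", paste(bad, collapse = ", "))
  switch(kind,
         logit = log((values + eps) / (1 - values + eps)),
         arcsine_sqrt = asin(sqrt(values)))
}

# pairwise-complete correlation matrix with t-approximation p-values
.cor_with_p <- function(A, B, method) {
  rk <- function(M) apply(M, 2L, function(v) { r <- rank(v, na.last = "keep"); r })
  if (method == "spearman") { A <- rk(A); B <- rk(B) }
  ra <- matrix(NA_real_, ncol(A), ncol(B),
               dimnames = list(colnames(A), colnames(B)))
  pv <- ra
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    ok <- stats::complete.cases(A[, i], B[, j])
    n <- sum(ok)
    if (n < 3L) next
    if (method == "spearman") {
      # re-rank within the complete pairs so midranks stay contiguous
      a <- rank(A[ok, i]); b <- rank(B[ok, j])
    } else { a <- A[ok, i]; b <- B[ok, j] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next  # constant: undefined
    r <- stats::cor(a, b)
    ra[i, j] <- r
    tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
    pv[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = ra, p = pv)
}

#' Correlation panels of structure counts and sizes
#'
#' The three correlation panels across slides: count vs count, size vs
#' size, and count (rows) vs size (columns), with p-values from the
#' standard t approximation.  Slides with undefined sizes (zero instances)
#' are handled pairwise-complete; constant columns yield `NA` entries.
#'
#' @param phenos slide phenotype table from [aggregate_slides()].
#' @param method `"pearson"` or `"spearman"` (midranks, rank-then-Pearson).
#' @param classes classes included (default the five AMF structures).
#' @return list of three elements `count_count`, `size_size`, `count_size`,
#'   each a list with matrices `r` and `p`.
#' @export
correlation_panel <- function(phenos, method = c("pearson", "spearman"),
                              classes = c("arb", "exH", "inH", "ves", "sp")) {
  method <- match.arg(method)
  if (nrow(phenos) < 3L) stop("need at least 3 slides")
  cnt <- as.matrix(phenos[, paste0("count_", classes), drop = FALSE])
  siz <- as.matrix(phenos[, paste0("avg_size_", classes), drop = FALSE])
  colnames(cnt) <- classes; colnames(siz) <- classes
  list(count_count = .cor_with_p(cnt, cnt, method),
       size_size = .cor_with_p(siz, siz, method),
       count_size = .cor_with_p(cnt, siz, method))
}

#' Write a slide phenotype table
#'
#' @param phenos table from [aggregate_slides()].
#' @param path output path (tab-delimited).
#' @param long also return a long-format (slide, variable, value) table?
#' @return the table written, invisibly (long format when `long = TRUE`).
#' @export
write_phenotypes <- function(phenos, path, long = FALSE) {
  out <- phenos
  if (long) {
    vars <- setdiff(names(phenos), "slide_id")
    out <- data.frame(
      slide_id = rep(phenos$slide_id, times = length(vars)),
      variable = rep(vars, each = nrow(phenos)),
      value = unlist(phenos[vars], use.names = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
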