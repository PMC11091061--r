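# Instance-segmentation evaluation: mask IoU, class-wise greedy matching,
# COCO-style average precision over IoU thresholds 0.50:0.05:0.95,
# confidence-score summaries and a class-frequency comparison.

#' Construct a mask instance
#'
#' A mask is a set of covered pixels, stored as 0-based integer pixel ids
#' (`id = x + y * width` for whatever raster the masks share).
#'
#' @param image_id image identifier.
#' @param class_label canonical class label.
#' @param pixels integer vector of pixel ids (non-empty).
#' @param confidence classifier confidence in `[0, 1]`; ground truth
#'   carries 1.
#' @return object of class `mask_instance`.
#' @export
mask_instance <- function(image_id, class_label, pixels, confidence = 1) {
  pixels <- unique(as.integer(pixels))
  if (!length(pixels)) stop("mask must be non-empty")
  if (confidence < 0 || confidence > 1) stop("confidence must be in [0, 1]")
  structure(list(image_id = as.character(image_id),
                 class_label = as.character(class_label),
                 pixels = sort(pixels), confidence = as.numeric(confidence)),
            class = "mask_instance")
}

#' Mask intersection over union
#'
#' @param a,b [mask_instance()] objects on the same image.
#' @return `|A intersect B| / |A union B|`.
#' @export
mask_iou <- function(a, b) {
  if (a$image_id != b$image_id) stop("masks belong to different images")
  ninter <- length(intersect(a$pixels, b$pixels))
  ninter / (length(a$pixels) + length(b$pixels) - ninter)
}

# greedy confidence-ordered matching of one class at one IoU threshold;
# returns per-prediction TP flags (preds already sorted) and counts
.match_class <- function(preds, truths, iou_threshold) {
  n_t <- length(truths)
  matched <- logical(n_t)
  tp <- logical(length(preds))
  for (pi in seq_along(preds)) {
    best <- 0; best_j <- 0L
    for (j in seq_len(n_t)) {
      if (matched[j]) next
      if (truths[[j]]$image_id != preds[[pi]]$image_id) next
      iou <- mask_iou(preds[[pi]], truths[[j]])
      if (iou >= iou_threshold && iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0L) { matched[best_j] <- TRUE; tp[pi] <- TRUE }
  }
  tp
}

# stable sort of predictions by descending confidence (ties keep input order)
.sort_preds <- function(preds) {
  conf <- vapply(preds, `[[`, 0, "confidence")
  preds[order(-conf)]
}

#' Average precision of one class at one IoU threshold
#'
#' Predictions are sorted by descending confidence (ties broken by input
#' order) and greedily matched one-to-one to unmatched ground-truth
#' instances of the same class and image with IoU at or above the
#' threshold.  AP is the area under the precision-recall curve, by default
#' the 101-point interpolated convention, reported on the 0-100 scale.
#'
#' @param preds,truths lists of [mask_instance()] objects (all classes;
#'   filtered internally).
#' @param class_label class to evaluate.
#' @param iou_threshold IoU threshold (default 0.5).
#' @param interpolation `"coco101"` (default) or `"exact"` (all-point
#'   integration).
#' @return AP in `[0, 100]`; `NA` when the class has no ground truth and no
#'   predictions, `0` when predictions exist without ground truth.
#' @export
average_precision <- function(preds, truths, class_label,
                              iou_threshold = 0.5,
                              interpolation = c("coco101", "exact")) {
  interpolation <- match.arg(interpolation)
  cl <- function(z) vapply(z, `[[`, "", "class_label") == class_label
  preds <- preds[cl(preds)]; truths <- truths[cl(truths)]
  if (!length(truths)) return(if (length(preds)) 0 else NA_real_)
  if (!length(preds)) return(0)
  preds <- .sort_preds(preds)
  tp <- .match_class(preds, truths, iou_threshold)
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  recall <- ctp / length(truths)
  precision <- ctp / (ctp + cfp)
  if (interpolation == "coco101") {
    # precision envelope sampled at recalls 0, 0.01, ..., 1
    rs <- seq(0, 1, by = 0.01)
    penv <- rev(cummax(rev(precision)))
    ap <- vapply(rs, function(r) {
      i <- which(recall >= r - 1e-12)
      if (length(i)) penv[i[1L]] else 0
    }, 0)
    return(100 * mean(ap))
  }
  # exact: sum precision-envelope area over recall steps
  penv <- rev(cummax(rev(precision)))
  r_prev <- 0; area <- 0
  for (i in seq_along(recall)) {
    if (recall[i] > r_prev) {
      area <- area + (recall[i] - r_prev) * penv[i]
      r_prev <- recall[i]
    }
  }
  100 * area
}

#' Full segmentation evaluation report
#'
#' Per-class AP averaged over the IoU thresholds, per-class AP50, their
#' class means mAP and mAP50 (over classes with at least one ground-truth
#' instance), and the predicted-vs-truth class frequency table.
#'
#' @param preds,truths lists of [mask_instance()] objects.
#' @param iou_thresholds IoU grid (default `seq(0.5, 0.95, 0.05)`).
#' @param classes classes to evaluate; defaults to all classes present in
#'   the ground truth.
#' @param interpolation passed to [average_precision()].
#' @return list with `per_class` (data.frame class, ap, ap50, n_truth,
#'   n_pred), `map`, `map50`, `iou_thresholds`.
#' @export
evaluate_segmentation <- function(preds, truths,
                                  iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                  classes = NULL,
                                  interpolation = "coco101") {
  tcl <- vapply(truths, `[[`, "", "class_label")
  pcl <- vapply(preds, `[[`, "", "class_label")
  if (is.null(classes)) classes <- sort(unique(tcl))
  rows <- lapply(classes, function(cl) {
    aps <- vapply(iou_thresholds, function(th)
      average_precision(preds, truths, cl, th, interpolation), 0)
    data.frame(class_label = cl, ap = mean(aps),
               ap50 = average_precision(preds, truths, cl, 0.5,
                                        interpolation),
               n_truth = sum(tcl == cl), n_pred = sum(pcl == cl),
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  with_gt <- per_class$n_truth > 0
  list(per_class = per_class,
       map = mean(per_class$ap[with_gt]),
       map50 = mean(per_class$ap50[with_gt]),
       iou_thresholds = iou_thresholds)
}

#' Confidence-score summary of predictions
#'
#' Retains predictions at or above the confidence threshold and summarizes
#' the per-class score distribution on `[threshold, 1]`: histogram counts
#' and sample skewness (negative for left-skewed, i.e. mass near 1).
#'
#' @param preds list of [mask_instance()] objects.
#' @param threshold confidence threshold (default 0.7).
#' @param n_bins number of histogram bins (default 10).
#' @return list per class: `counts`, `breaks`, `skewness`, `n`.
#' @export
confidence_summary <- function(preds, threshold = 0.7, n_bins = 10L) {
  conf <- vapply(preds, `[[`, 0, "confidence")
  cls <- vapply(preds, `[[`, "", "class_label")
  keep <- conf >= threshold
  conf <- conf[keep]; cls <- cls[keep]
  breaks <- seq(threshold, 1, length.out = n_bins + 1L)
  out <- list()
  for (cl in sort(unique(cls))) {
    v <- conf[cls == cl]
    h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
    out[[cl]] <- list(counts = h$counts, breaks = breaks,
                      skewness = sample_skewness(v), n = length(v))
  }
  out
}

#' Compare predicted and human-scored class frequencies
#'
#' Fisher's exact test on the 2 x K contingency table of per-class counts:
#' exact enumeration when feasible, otherwise a seeded Monte-Carlo
#' approximation (the method used is reported).
#'
#' @param pred_counts,truth_counts named per-class count vectors over the
#'   same class set.
#' @param seed seed for the Monte-Carlo path.
#' @param B Monte-Carlo replicates (default 1e5).
#' @return list with `p` and `method` (`"exact"` or `"monte-carlo"`).
#' @export
compare_class_frequencies <- function(pred_counts, truth_counts,
                                      seed = 1L, B = 1e5) {
  if (!identical(sort(names(pred_counts)), sort(names(truth_counts))))
    stop("pred and truth counts must cover the same class set")
  truth_counts <- truth_counts[names(pred_counts)]
  tab <- rbind(pred = pred_counts, truth = truth_counts)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (!sum(tab)) stop("all-zero contingency table")
  res <- tryCatch(
    list(p = stats::fisher.test(tab, workspace = 2e7)$p.value,
         method = "exact"),
    error = function(e) NULL)
  if (is.null(res))
    res <- list(p = with_seed(seed,
                  stats::fisher.test(tab, simulate.p.value = TRUE,
                                     B = B)$p.value),
                method = "monte-carlo")
  res
}
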