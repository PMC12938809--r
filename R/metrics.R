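# Detection metrics (IoU, precision/recall/F1, average precision, mAP),
# circle-error summaries, and normalized tolerance-accuracy curves.

#' Intersection-over-Union of two boxes
#'
#' @param a,b [roi_box()] objects.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "roi_box"), inherits(b, "roi_box"))
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  if (union <= 0) 0 else inter / union
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching per class in descending confidence: a
#' prediction above the confidence threshold is a true positive when its best
#' remaining IoU with an unmatched same-class truth reaches `iou_tau`.
#'
#' @param preds,truths Lists of [roi_box()].
#' @param conf_t Confidence threshold in \[0, 1\].
#' @param iou_tau IoU threshold in \[0, 1\].
#' @return List of class `match_counts` with integer fields tp, fp, fn.
#' @export
match_detections <- function(preds, truths, conf_t = 0.25, iou_tau = 0.5) {
  preds <- Filter(function(p) p$confidence >= conf_t, preds)
  tp <- 0L
  fp <- 0L
  classes <- unique(c(
    vapply(preds, function(b) as.integer(b$cls), 1L),
    vapply(truths, function(b) as.integer(b$cls), 1L)
  ))
  fn <- 0L
  for (cl in classes) {
    p_cl <- Filter(function(b) identical(as.integer(b$cls), cl), preds)
    t_cl <- Filter(function(b) identical(as.integer(b$cls), cl), truths)
    if (length(p_cl) > 0) {
      ord <- order(-vapply(p_cl, function(b) b$confidence, 0))
      p_cl <- p_cl[ord]
    }
    used <- rep(FALSE, length(t_cl))
    for (p in p_cl) {
      ious <- vapply(seq_along(t_cl), function(i) {
        if (used[i]) -1 else iou(p, t_cl[[i]])
      }, 0)
      if (length(ious) > 0 && max(ious) >= iou_tau) {
        used[which.max(ious)] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!used)
  }
  structure(list(tp = tp, fp = fp, fn = fn), class = "match_counts")
}

#' Precision, recall and F1 from match counts
#'
#' Degenerate denominators follow the usual conventions: precision = 0 when
#' tp + fp = 0, recall = 0 when tp + fn = 0, F1 = 0 when both are 0.
#'
#' @param m A `match_counts` list (fields tp, fp, fn).
#' @return Named numeric: precision, recall, f1.
#' @export
precision_recall_f1 <- function(m) {
  p <- if (m$tp + m$fp == 0) 0 else m$tp / (m$tp + m$fp)
  r <- if (m$tp + m$fn == 0) 0 else m$tp / (m$tp + m$fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Average precision from a ranked detection list
#'
#' Sweeps the confidence threshold downward and integrates the all-points
#' precision-recall curve (AP = sum of precision x recall increments over
#' distinct confidence levels).
#'
#' @param scored Data frame (or list) with numeric `confidence` and logical
#'   `is_tp` per detection.
#' @param n_truth Number of ground-truth instances (>= 0).
#' @return List of class `pr_curve` with `points` (data.frame of recall,
#'   precision, ordered by recall) and `ap`.
#' @export
average_precision <- function(scored, n_truth) {
  scored <- as.data.frame(scored)
  if (n_truth < 0) hw_error("n_truth must be >= 0", "parameter")
  if (nrow(scored) == 0 || n_truth == 0) {
    return(structure(
      list(points = data.frame(recall = numeric(0), precision = numeric(0)),
           ap = 0),
      class = "pr_curve"
    ))
  }
  o <- order(-scored$confidence)
  conf <- scored$confidence[o]
  tp <- cumsum(scored$is_tp[o])
  fp <- cumsum(!scored$is_tp[o])
  # Evaluate only at distinct confidence levels (last index of each block).
  last <- which(c(conf[-1] != conf[-length(conf)], TRUE))
  recall <- tp[last] / n_truth
  precision <- tp[last] / (tp[last] + fp[last])
  ap <- sum(diff(c(0, recall)) * precision)
  structure(
    list(points = data.frame(recall = recall, precision = precision), ap = ap),
    class = "pr_curve"
  )
}

#' Mean average precision over classes
#'
#' @param aps Numeric vector of per-class AP values.
#' @return Arithmetic mean.
#' @export
mean_ap <- function(aps) {
  if (length(aps) == 0) hw_error("empty AP list", "empty_input")
  mean(aps)
}

#' Tolerance-accuracy curve
#'
#' For each tolerance, the fraction of errors at or below it. Monotone
#' non-decreasing by construction.
#'
#' @param errors Numeric vector of normalized errors (non-empty).
#' @param tolerances Ascending numeric vector of tolerances.
#' @return Data frame with columns tolerance, accuracy.
#' @export
tolerance_accuracy_curve <- function(errors, tolerances) {
  if (length(errors) == 0) hw_error("empty error list", "empty_input")
  if (is.unsorted(tolerances)) {
    hw_error("tolerances must be sorted ascending", "parameter")
  }
  data.frame(
    tolerance = tolerances,
    accuracy = vapply(tolerances, function(t) mean(errors <= t), 0)
  )
}

#' Error summary statistics
#'
#' Mean, sample standard deviation, median, 95th percentile (linear
#' interpolation between order statistics) and maximum.
#'
#' @param errors Non-empty numeric vector.
#' @return List of class `error_summary`.
#' @export
error_summary <- function(errors) {
  if (length(errors) == 0) hw_error("empty error list", "empty_input")
  structure(
    list(
      mean = mean(errors),
      std = if (length(errors) > 1) stats::sd(errors) else 0,
      median = stats::median(errors),
      p95 = stats::quantile(errors, 0.95, names = FALSE),
      max = max(errors)
    ),
    class = "error_summary"
  )
}

#' Normalized circle errors between a fitted and a true circle
#'
#' Center error = Euclidean center distance / ((W + H) / 2); radius error =
#' |delta r| / ((W + H) / 2) — the same mean-dimension scaling used by the
#' annotation normalization.
#'
#' @param fit,truth [circle()] objects in pixel space.
#' @param dims An [image_dims()].
#' @return Named numeric: center, radius.
#' @export
normalized_circle_errors <- function(fit, truth, dims) {
  s <- (dims$W + dims$H) / 2
  c(
    center = sqrt((fit$cx - truth$cx)^2 + (fit$cy - truth$cy)^2) / s,
    radius = abs(fit$r - truth$r) / s
  )
}
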