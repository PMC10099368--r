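# Detection evaluation: IoU, non-maximum suppression, greedy matching,
# precision/recall, average precision over the PR curve, mAP over the
# 0.5:0.05:0.95 IoU threshold grid, PR curves and confusion matrix.
#
# Detections are data.frames with columns x1, y1, x2, y2 (pixel xyxy),
# conf, class_id, and (for multi-image evaluation) image. Ground truth has
# x1, y1, x2, y2, class_id, image.

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b numeric length-4 vectors `(x1, y1, x2, y2)`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / ua
}

# IoU matrix between rows of A and rows of B (n x 4 matrices)
iou_matrix <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(matrix(0, nrow(A), nrow(B)))
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    iw <- pmin(A[i, 3], B[, 3]) - pmax(A[i, 1], B[, 1])
    ih <- pmin(A[i, 4], B[, 4]) - pmax(A[i, 2], B[, 2])
    inter <- pmax(iw, 0) * pmax(ih, 0)
    ua <- (A[i, 3] - A[i, 1]) * (A[i, 4] - A[i, 2]) +
      (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
    out[i, ] <- ifelse(ua > 0, inter / ua, 0)
  }
  out
}

det_boxes <- function(d) as.matrix(d[, c("x1", "y1", "x2", "y2")])

#' Non-maximum suppression
#'
#' Greedy per-class suppression: detections below `conf_thresh` are dropped,
#' survivors are sorted by confidence and any same-class box overlapping a
#' kept box above `iou_thresh` is removed.
#'
#' @param dets detection data.frame.
#' @param iou_thresh IoU threshold in `[0, 1]`.
#' @param conf_thresh confidence threshold in `[0, 1]`.
#' @return the surviving detections, sorted by confidence (descending).
#' @export
nms <- function(dets, iou_thresh = 0.45, conf_thresh = 0.25) {
  stopifnot(iou_thresh >= 0, iou_thresh <= 1)
  dets <- dets[dets$conf >= conf_thresh, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  dets <- dets[order(-dets$conf), , drop = FALSE]
  keep <- logical(nrow(dets))
  boxes <- det_boxes(dets)
  for (i in seq_len(nrow(dets))) {
    if (i > 1) {
      prev <- which(keep[seq_len(i - 1)] &
                      dets$class_id[seq_len(i - 1)] == dets$class_id[i])
      if (length(prev) > 0) {
        ious <- vapply(prev, function(j) iou(boxes[i, ], boxes[j, ]),
                       numeric(1))
        if (any(ious > iou_thresh)) next
      }
    }
    keep[i] <- TRUE
  }
  dets[keep, , drop = FALSE]
}

# greedy confidence-descending one-to-one matching within one image and one
# class; returns logical TP flag per detection (dets assumed conf-sorted)
greedy_match_flags <- function(det_b, truth_b, iou_threshold) {
  n <- nrow(det_b)
  flags <- logical(n)
  if (n == 0) return(flags)
  used <- logical(nrow(truth_b))
  if (nrow(truth_b) > 0) {
    M <- iou_matrix(det_b, truth_b)
    for (i in seq_len(n)) {
      cand <- which(!used & M[i, ] >= iou_threshold)
      if (length(cand) > 0) {
        best <- cand[which.max(M[i, cand])]
        used[best] <- TRUE
        flags[i] <- TRUE
      }
    }
  }
  flags
}

#' Match detections to ground truth, tallying TP/FP/FN per class
#'
#' Greedy confidence-descending one-to-one matching per class (and per
#' image when an `image` column is present): a detection is a true positive
#' if it overlaps an unused same-class truth at IoU >= threshold; unmatched
#' detections are false positives, unmatched truths false negatives.
#' `TP + FN` equals the ground-truth count of each class.
#'
#' @param dets NMS-filtered detections.
#' @param truths ground-truth boxes.
#' @param iou_threshold IoU threshold.
#' @param num_classes number of classes (defaults to the largest id seen).
#' @return data.frame `class_id, tp, fp, fn` with class `uw_match_tally`.
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5,
                             num_classes = NULL) {
  if (is.null(num_classes)) {
    num_classes <- max(c(dets$class_id, truths$class_id, 0)) + 1
  }
  if (is.null(dets$image)) dets$image <- rep("img", nrow(dets))
  if (is.null(truths$image)) truths$image <- rep("img", nrow(truths))
  tal <- data.frame(class_id = seq_len(num_classes) - 1L, tp = 0L, fp = 0L,
                    fn = 0L)
  for (cls in tal$class_id) {
    for (im in unique(c(dets$image, truths$image))) {
      d <- dets[dets$class_id == cls & dets$image == im, , drop = FALSE]
      d <- d[order(-d$conf), , drop = FALSE]
      t <- truths[truths$class_id == cls & truths$image == im, , drop = FALSE]
      flags <- greedy_match_flags(det_boxes(d), det_boxes(t), iou_threshold)
      i <- cls + 1L
      tal$tp[i] <- tal$tp[i] + sum(flags)
      tal$fp[i] <- tal$fp[i] + sum(!flags)
      tal$fn[i] <- tal$fn[i] + nrow(t) - sum(flags)
    }
  }
  class(tal) <- c("uw_match_tally", class(tal))
  tal
}

#' Precision from a match tally
#'
#' `TP / (TP + FP)`, summed over classes; 0 when no detections were made.
#'
#' @param t a match tally (or any list with `tp` and `fp`).
#' @return precision in `[0, 1]`.
#' @export
precision <- function(t) {
  tp <- sum(t$tp)
  fp <- sum(t$fp)
  if (tp + fp == 0) 0 else tp / (tp + fp)
}

#' Recall from a match tally
#'
#' `TP / (TP + FN)`, summed over classes; 0 when there is no ground truth.
#'
#' @param t a match tally (or any list with `tp` and `fn`).
#' @return recall in `[0, 1]`.
#' @export
recall <- function(t) {
  tp <- sum(t$tp)
  fn <- sum(t$fn)
  if (tp + fn == 0) 0 else tp / (tp + fn)
}

#' Average precision for one class
#'
#' Area under the precision-recall curve built from confidence-ranked
#' detections of one class. The default integrator is 101-point
#' interpolation (precision envelope sampled at recalls 0, 0.01, ..., 1);
#' `method = "continuous"` integrates the envelope by trapezoids over the
#' exact recall breakpoints.
#'
#' @param dets detections of one class, any order (ranked internally by
#'   confidence); must carry `image` when truths span several images.
#' @param truths ground-truth boxes of the same class.
#' @param iou_threshold IoU threshold for a true positive.
#' @param method `"interp101"` or `"continuous"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, truths, iou_threshold = 0.5,
                              method = c("interp101", "continuous")) {
  method <- match.arg(method)
  n_gt <- nrow(truths)
  if (n_gt == 0) return(0)
  if (nrow(dets) == 0) return(0)
  if (is.null(dets$image)) dets$image <- rep("img", nrow(dets))
  if (is.null(truths$image)) truths$image <- rep("img", nrow(truths))
  dets <- dets[order(-dets$conf), , drop = FALSE]
  flags <- logical(nrow(dets))
  for (im in unique(dets$image)) {
    sel <- which(dets$image == im)
    t <- truths[truths$image == im, , drop = FALSE]
    flags[sel] <- greedy_match_flags(det_boxes(dets[sel, , drop = FALSE]),
                                     det_boxes(t), iou_threshold)
  }
  if (!any(flags)) return(0)
  tp_cum <- cumsum(flags)
  fp_cum <- cumsum(!flags)
  rec <- tp_cum / n_gt
  prec <- tp_cum / (tp_cum + fp_cum)
  ap_from_curve(rec, prec, method)
}

ap_from_curve <- function(rec, prec, method = "interp101") {
  # precision envelope: running max from the right
  rec <- c(0, rec)
  prec <- c(1, prec)
  env <- rev(cummax(rev(prec)))
  if (method == "interp101") {
    grid <- seq(0, 1, by = 0.01)
    vals <- vapply(grid, function(r) {
      ix <- which(rec >= r)
      if (length(ix) == 0) 0 else env[ix[1]]
    }, numeric(1))
    mean(vals)
  } else {
    sum(diff(rec) * env[-1])
  }
}

#' Mean average precision over classes (and IoU thresholds)
#'
#' The arithmetic mean of per-class APs. Given a matrix (classes x
#' thresholds over the grid 0.5, 0.55, ..., 0.95) it also returns the
#' threshold-averaged mAP.
#'
#' @param per_class_ap numeric vector (one AP per class at IoU 0.5) or a
#'   classes-by-10 matrix over the threshold grid.
#' @return list with `map50` and (for a matrix) `map50_95`.
#' @export
mean_ap <- function(per_class_ap) {
  if (is.matrix(per_class_ap)) {
    stopifnot(ncol(per_class_ap) == length(iou_threshold_grid()))
    list(map50 = mean(per_class_ap[, 1]), map50_95 = mean(per_class_ap))
  } else {
    list(map50 = mean(per_class_ap), map50_95 = NA_real_)
  }
}

#' The standard IoU threshold grid 0.5, 0.55, ..., 0.95
#' @return numeric vector of 10 thresholds.
#' @export
iou_threshold_grid <- function() seq(0.5, 0.95, by = 0.05)

#' Confusion matrix with background row/column
#'
#' `(num_classes + 1)^2` matrix; rows are the true label, columns the
#' prediction, with the last row/column standing for background: unmatched
#' truths count into the background column, unmatched detections into the
#' background row. Matching is greedy by IoU across classes at
#' `iou_threshold` after dropping detections below `conf_threshold`.
#'
#' @param dets detections.
#' @param truths ground truth.
#' @param num_classes class count.
#' @param iou_threshold IoU threshold.
#' @param conf_threshold confidence threshold.
#' @return integer matrix with dimnames.
#' @export
confusion_matrix <- function(dets, truths, num_classes,
                             iou_threshold = 0.45, conf_threshold = 0.25) {
  cm <- matrix(0L, num_classes + 1, num_classes + 1)
  lab <- c(paste0("class", seq_len(num_classes) - 1), "background")
  dimnames(cm) <- list(truth = lab, prediction = lab)
  dets <- dets[dets$conf >= conf_threshold, , drop = FALSE]
  if (is.null(dets$image)) dets$image <- rep("img", nrow(dets))
  if (is.null(truths$image)) truths$image <- rep("img", nrow(truths))
  for (im in unique(c(dets$image, truths$image))) {
    d <- dets[dets$image == im, , drop = FALSE]
    d <- d[order(-d$conf), , drop = FALSE]
    t <- truths[truths$image == im, , drop = FALSE]
    used <- logical(nrow(t))
    M <- iou_matrix(det_boxes(d), det_boxes(t))
    for (i in seq_len(nrow(d))) {
      cand <- which(!used & M[i, ] >= iou_threshold)
      if (length(cand) > 0) {
        best <- cand[which.max(M[i, cand])]
        used[best] <- TRUE
        cm[t$class_id[best] + 1, d$class_id[i] + 1] <-
          cm[t$class_id[best] + 1, d$class_id[i] + 1] + 1L
      } else {
        cm[num_classes + 1, d$class_id[i] + 1] <-
          cm[num_classes + 1, d$class_id[i] + 1] + 1L
      }
    }
    for (j in which(!used)) {
      cm[t$class_id[j] + 1, num_classes + 1] <-
        cm[t$class_id[j] + 1, num_classes + 1] + 1L
    }
  }
  cm
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP over the 0.5:0.05:0.95 IoU grid, mAP\@0.5 and
#' mAP\@0.5:0.95, PR curves at IoU 0.5, and the confusion matrix.
#'
#' @param dets detections over a dataset (with `image` column).
#' @param truths ground truth (with `image` column).
#' @param num_classes class count.
#' @param ap_method AP integrator, see [average_precision()].
#' @return an `uw_eval_report`: list with `ap` (classes x thresholds
#'   matrix), `map50`, `map50_95`, `pr_curves`, `confusion`.
#' @export
evaluate_detections <- function(dets, truths, num_classes,
                                ap_method = "interp101") {
  grid <- iou_threshold_grid()
  ap <- matrix(0, num_classes, length(grid),
               dimnames = list(paste0("class", seq_len(num_classes) - 1),
                               sprintf("iou%.2f", grid)))
  pr_curves <- vector("list", num_classes)
  for (cls in seq_len(num_classes) - 1L) {
    d <- dets[dets$class_id == cls, , drop = FALSE]
    t <- truths[truths$class_id == cls, , drop = FALSE]
    for (k in seq_along(grid)) {
      ap[cls + 1, k] <- average_precision(d, t, grid[k], method = ap_method)
    }
    if (nrow(d) > 0 && nrow(t) > 0) {
      d <- d[order(-d$conf), , drop = FALSE]
      flags <- logical(nrow(d))
      for (im in unique(d$image)) {
        sel <- which(d$image == im)
        flags[sel] <- greedy_match_flags(
          det_boxes(d[sel, , drop = FALSE]),
          det_boxes(t[t$image == im, , drop = FALSE]), 0.5)
      }
      pr_curves[[cls + 1]] <- data.frame(
        conf = d$conf, recall = cumsum(flags) / nrow(t),
        precision = cumsum(flags) / seq_len(nrow(d)))
    } else {
      pr_curves[[cls + 1]] <- data.frame(conf = numeric(0),
                                         recall = numeric(0),
                                         precision = numeric(0))
    }
  }
  m <- mean_ap(ap)
  structure(list(ap = ap, map50 = m$map50, map50_95 = m$map50_95,
                 pr_curves = pr_curves,
                 confusion = confusion_matrix(dets, truths, num_classes)),
            class = "uw_eval_report")
}

#' @export
print.uw_eval_report <- function(x, ...) {
  cat("<uw_eval_report>\n")
  cat(sprintf("  mAP@0.5      %.4f\n", x$map50))
  cat(sprintf("  mAP@0.5:0.95 %.4f\n", x$map50_95))
  cat("  per-class AP@0.5:",
      paste(sprintf("%.3f", x$ap[, 1]), collapse = " "), "\n")
  invisible(x)
}

#' Plot PR curves of an evaluation report
#'
#' @param report an `uw_eval_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_pr_curves <- function(report, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "recall",
                 ylab = "precision", main = "PR curves (IoU 0.5)", ...)
  for (i in seq_along(report$pr_curves)) {
    pc <- report$pr_curves[[i]]
    if (nrow(pc) > 0) {
      graphics::lines(c(0, pc$recall), c(1, pc$precision), col = i)
    }
  }
  graphics::legend("bottomleft", legend = rownames(report$ap),
                   col = seq_len(nrow(report$ap)), lty = 1, cex = 0.7)
  invisible(report)
}

#' Plot the confusion matrix of an evaluation report
#'
#' @param report an `uw_eval_report`.
#' @export
plot_confusion_matrix <- function(report) {
  cm <- report$confusion
  n <- nrow(cm)
  graphics::image(seq_len(n), seq_len(n), t(cm[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "prediction", ylab = "truth",
                  main = "confusion matrix")
  graphics::axis(1, seq_len(n), colnames(cm), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(cm)), las = 2, cex.axis = 0.7)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    graphics::text(j, n + 1 - i, cm[i, j], cex = 0.8)
  }
  invisible(report)
}
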