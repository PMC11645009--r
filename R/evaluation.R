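# Detection-style evaluation: IoU, precision/recall, per-class average
# precision by all-point PR-curve integration, and mAP at IoU 0.5.

#' Intersection over union of two normalized boxes
#'
#' @param a,b Numeric length-4 boxes `(x1, y1, x2, y2)`.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
box_iou <- function(a, b) {
  validate_box(a); validate_box(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

# vectorized IoU of one box against an n x 4 matrix
iou_one_many <- function(a, B) {
  if (nrow(B) == 0L) return(numeric(0))
  ix <- pmax(0, pmin(a[3], B[, 3]) - pmax(a[1], B[, 1]))
  iy <- pmax(0, pmin(a[4], B[, 4]) - pmax(a[2], B[, 2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (area_a + area_b - inter)
}

#' Precision and recall from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; when a denominator is zero the
#' metric is reported as 0 and flagged.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return List with `precision`, `recall`, and logical flags
#'   `precision_defined`, `recall_defined`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  pd <- (tp + fp) > 0
  rd <- (tp + fn) > 0
  list(precision = if (pd) tp / (tp + fp) else 0,
       recall = if (rd) tp / (tp + fn) else 0,
       precision_defined = pd, recall_defined = rd)
}

#' Average precision for one class of scored detections
#'
#' Detections are swept in descending score order (ties broken by input
#' order); each is greedily matched to the highest-IoU unclaimed ground-truth
#' box in the same (video, second) with IoU >= `iou_thr`. AP is the area under
#' the resulting precision-recall curve with all-point interpolation
#' (precision envelope made monotone from the right).
#'
#' @param dets data.frame with `video_id`, `timestamp_s`, `x1..y2`, `score`.
#' @param gts data.frame of ground-truth boxes with `video_id`, `timestamp_s`,
#'   `x1..y2` (one row per GT instance of this class).
#' @param iou_thr IoU threshold (default 0.5).
#' @return List with `ap`, and the sweep's `precision`, `recall`, `tp`, `fp`.
#' @export
average_precision <- function(dets, gts, iou_thr = 0.5) {
  n_gt <- nrow(gts)
  if (nrow(dets) == 0L)
    return(list(ap = 0, precision = numeric(0), recall = numeric(0),
                tp = 0L, fp = 0L))
  if (n_gt == 0L)
    return(list(ap = 0, precision = rep(0, nrow(dets)),
                recall = rep(0, nrow(dets)), tp = 0L, fp = nrow(dets)))
  ord <- order(-dets$score, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  claimed <- rep(FALSE, n_gt)
  is_tp <- logical(nrow(dets))
  gtb <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  gkey <- paste(gts$video_id, gts$timestamp_s)
  dkey <- paste(dets$video_id, dets$timestamp_s)
  for (i in seq_len(nrow(dets))) {
    cand <- which(gkey == dkey[i] & !claimed)
    if (length(cand) == 0L) next
    ious <- iou_one_many(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                         gtb[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_thr) {
      claimed[cand[j]] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  tp_cum <- cumsum(is_tp)
  fp_cum <- cumsum(!is_tp)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_gt
  # all-point interpolation: running max of precision from the right
  env <- rev(cummax(rev(prec)))
  r_prev <- c(0, rec[-length(rec)])
  list(ap = sum((rec - r_prev) * env),
       precision = prec, recall = rec,
       tp = sum(is_tp), fp = sum(!is_tp))
}

#' Evaluate multi-label box predictions against AVA-style ground truth
#'
#' Each prediction row carries a box and a score per class; every
#' (box, class, score) is treated as one scored detection for that class and
#' scored against the class's ground-truth boxes via [average_precision()] at
#' the given IoU threshold. mAP is the mean AP over classes with positive
#' ground-truth support. Precision and recall are reported at the score-0.5
#' operating point (only detections scoring at least 0.5 for the class count
#' as predicted positives). Because the AP metric is rank-based, a thresholded
#' per-class accuracy (decision at score >= 0.5 on IoU-matched boxes, missed
#' ground truth counted as errors for its positive classes) is reported
#' alongside, labeled distinctly.
#'
#' @param predictions data.frame with `video_id`, `timestamp_s`, `x1..y2`, and
#'   either score columns `score_1..score_C` or long-format `action_id`,
#'   `score`.
#' @param gts Validated `ava_records` ground truth.
#' @param labels Label map.
#' @param iou_thr IoU threshold (default 0.5).
#' @return An `eval_summary`: list with `per_class` (data.frame of AP,
#'   precision, recall, accuracy, support per label) and `mAP`.
#' @export
evaluate_predictions <- function(predictions, gts,
                                 labels = default_label_map(),
                                 iou_thr = 0.5) {
  labels <- validate_label_map(labels)
  gts <- validate_ava_records(gts, labels)
  if (nrow(gts) == 0L) stop("empty ground truth")
  C <- nrow(labels)
  preds_long <- predictions_to_long(predictions, C)

  per <- data.frame(id = labels$id, name = labels$name,
                    AP = NA_real_, precision = NA_real_, recall = NA_real_,
                    accuracy = NA_real_, support = 0L)
  for (ci in seq_len(C)) {
    cid <- labels$id[ci]
    g <- gts[gts$action_id == cid, , drop = FALSE]
    d <- preds_long[preds_long$action_id == cid, , drop = FALSE]
    per$support[ci] <- nrow(g)
    res <- average_precision(d, g, iou_thr)
    per$AP[ci] <- res$ap
    # P/R from confusion counts at the score-0.5 operating point
    d05 <- d[d$score >= 0.5, , drop = FALSE]
    res05 <- average_precision(d05, g, iou_thr)
    pr <- precision_recall(res05$tp, res05$fp, max(0, nrow(g) - res05$tp))
    per$precision[ci] <- pr$precision
    per$recall[ci] <- pr$recall
  }
  per$accuracy <- thresholded_accuracy(preds_long, gts, labels, iou_thr)
  has_support <- per$support > 0
  out <- list(per_class = per,
              mAP = mean(per$AP[has_support]),
              iou_threshold = iou_thr)
  class(out) <- "eval_summary"
  out
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("mAP@%.2f = %.4f over %d classes\n", x$iou_threshold, x$mAP,
              sum(x$per_class$support > 0)))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

predictions_to_long <- function(predictions, C) {
  base_cols <- c("video_id", "timestamp_s", "x1", "y1", "x2", "y2")
  if (all(c("action_id", "score") %in% names(predictions))) {
    return(predictions[, c(base_cols, "action_id", "score")])
  }
  score_cols <- paste0("score_", seq_len(C))
  if (!all(score_cols %in% names(predictions)))
    stop("predictions need either long-format action_id/score or columns ",
         paste(score_cols, collapse = ", "))
  long <- do.call(rbind, lapply(seq_len(C), function(ci) {
    df <- predictions[, base_cols]
    df$action_id <- ci
    df$score <- predictions[[score_cols[ci]]]
    df
  }))
  rownames(long) <- NULL
  long
}

# decision-at-0.5 accuracy per class over GT-matched boxes; a GT box with no
# matched prediction counts as a wrong decision for each of its positive labels
thresholded_accuracy <- function(preds_long, gts, labels, iou_thr) {
  C <- nrow(labels)
  gkey <- unique(gts[, c("video_id", "timestamp_s", "entity_id")])
  correct <- integer(C); total <- integer(C)
  pboxes <- unique(preds_long[, c("video_id", "timestamp_s",
                                  "x1", "y1", "x2", "y2")])
  for (i in seq_len(nrow(gkey))) {
    grows <- gts[gts$video_id == gkey$video_id[i] &
                 gts$timestamp_s == gkey$timestamp_s[i] &
                 gts$entity_id == gkey$entity_id[i], , drop = FALSE]
    gbox <- as.numeric(grows[1, c("x1", "y1", "x2", "y2")])
    truth <- seq_len(C) %in% grows$action_id
    cand <- pboxes[pboxes$video_id == gkey$video_id[i] &
                   pboxes$timestamp_s == gkey$timestamp_s[i], , drop = FALSE]
    matched <- FALSE
    if (nrow(cand) > 0L) {
      ious <- iou_one_many(gbox, as.matrix(cand[, c("x1", "y1", "x2", "y2")]))
      j <- which.max(ious)
      if (ious[j] >= iou_thr) {
        matched <- TRUE
        sel <- preds_long$video_id == cand$video_id[j] &
          preds_long$timestamp_s == cand$timestamp_s[j] &
          preds_long$x1 == cand$x1[j] & preds_long$y1 == cand$y1[j] &
          preds_long$x2 == cand$x2[j] & preds_long$y2 == cand$y2[j]
        sc <- rep(0, C)
        sub <- preds_long[sel, ]
        sc[sub$action_id] <- sub$score
        decision <- sc >= 0.5
        hit <- decision == truth
      }
    }
    if (!matched) hit <- !truth  # every positive label is missed
    total <- total + 1L
    correct <- correct + as.integer(hit)
  }
  ifelse(total > 0, correct / total, NA_real_)
}
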