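test_that("IoU matches hand-computed overlaps", {
  expect_equal(box_iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(box_iou(c(0, 0, 0.4, 0.4), c(0.5, 0.5, 0.9, 0.9)), 0)
  expect_equal(box_iou(c(0, 0, 1, 1), c(0.5, 0, 1, 1)), 0.5)
  # congruent boxes shifted by half their width: intersection/union = 1/3
  expect_equal(box_iou(c(0, 0, 0.5, 0.5), c(0.25, 0, 0.75, 0.5)),
               1 / 3, tolerance = 1e-12)
})

test_that("IoU is symmetric and bounded by the area ratio", {
  set.seed(21)
  for (i in 1:50) {
    a <- c(sort(runif(2)), sort(runif(2)))[c(1, 3, 2, 4)]
    b <- c(sort(runif(2)), sort(runif(2)))[c(1, 3, 2, 4)]
    if (a[1] == a[3] || a[2] == a[4] || b[1] == b[3] || b[2] == b[4]) next
    expect_equal(box_iou(a, b), box_iou(b, a))
    area <- function(x) (x[3] - x[1]) * (x[4] - x[2])
    expect_lte(box_iou(a, b),
               min(area(a), area(b)) / max(area(a), area(b)) + 1e-12)
  }
})

test_that("precision and recall follow the confusion-count formulas", {
  pr <- precision_recall(8, 2, 4)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 2 / 3)
  pr2 <- precision_recall(5, 0, 0)
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))
  pr3 <- precision_recall(0, 3, 0)
  expect_equal(pr3$precision, 0)
  expect_false(pr3$recall_defined)
})

test_that("average precision integrates the hand-built PR curve", {
  gts <- data.frame(video_id = "v", timestamp_s = 1,
                    x1 = c(0.0, 0.6), y1 = c(0.0, 0.6),
                    x2 = c(0.3, 0.9), y2 = c(0.3, 0.9))
  dets <- data.frame(video_id = "v", timestamp_s = 1,
                     x1 = c(0.0, 0.35, 0.6), y1 = c(0.0, 0.35, 0.6),
                     x2 = c(0.3, 0.55, 0.9), y2 = c(0.3, 0.55, 0.9),
                     score = c(0.9, 0.8, 0.7))
  # sweep: TP (P=1,R=.5), FP (P=.5,R=.5), TP (P=2/3,R=1) => AP = 5/6
  res <- average_precision(dets, gts, 0.5)
  expect_equal(res$ap, 5 / 6, tolerance = 1e-12)
  expect_equal(res$tp, 2)

  # perfect detections: AP = 1; no detections: AP = 0
  perfect <- cbind(gts, score = c(0.9, 0.8))
  expect_equal(average_precision(perfect, gts)$ap, 1)
  expect_equal(average_precision(dets[0, ], gts)$ap, 0)
})

test_that("average precision agrees with brute-force integration on all
           orderings of small detection sets", {
  set.seed(8)
  for (rep in 1:30) {
    n_gt <- sample(1:3, 1)
    n_det <- sample(1:5, 1)
    # GT boxes on a grid so overlaps are controlled
    gts <- data.frame(video_id = "v", timestamp_s = 0,
                      x1 = (seq_len(n_gt) - 1) * 0.3, y1 = 0,
                      x2 = (seq_len(n_gt) - 1) * 0.3 + 0.25, y2 = 0.25)
    # detections: some copies of GT boxes, some disjoint boxes
    src <- sample(n_gt + 2, n_det, replace = TRUE)
    dets <- do.call(rbind, lapply(src, function(s) {
      if (s <= n_gt) gts[s, ] else
        data.frame(video_id = "v", timestamp_s = 0, x1 = 0.1 + 0.05 * s,
                   y1 = 0.6, x2 = 0.3 + 0.05 * s, y2 = 0.9)
    }))
    dets$score <- round(runif(n_det), 3)
    res <- average_precision(dets, gts, 0.5)
    # oracle: replay the same greedy matching decisions, then integrate the
    # PR curve from scratch
    ord <- order(-dets$score, seq_len(n_det))
    claimed <- rep(FALSE, n_gt)
    is_tp <- logical(n_det)
    for (i in ord) {
      ious <- vapply(seq_len(n_gt), function(g)
        if (claimed[g]) -1 else
          box_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                  as.numeric(gts[g, c("x1", "y1", "x2", "y2")])),
        numeric(1))
      j <- which.max(ious)
      if (ious[j] >= 0.5) { claimed[j] <- TRUE; is_tp[which(ord == i)] <- TRUE }
    }
    expect_equal(res$ap, brute_force_ap(is_tp, n_gt), tolerance = 1e-12)
  }
})

test_that("AP is invariant to positive monotone score transforms", {
  set.seed(3)
  gts <- data.frame(video_id = "v", timestamp_s = 0,
                    x1 = c(0, 0.5), y1 = c(0, 0.5),
                    x2 = c(0.4, 0.9), y2 = c(0.4, 0.9))
  dets <- rbind(gts, data.frame(video_id = "v", timestamp_s = 0, x1 = 0.05,
                                y1 = 0.55, x2 = 0.45, y2 = 0.95))
  dets$score <- c(0.7, 0.2, 0.5)
  ap1 <- average_precision(dets, gts)$ap
  dets$score <- exp(3 * dets$score) / 10  # strictly increasing transform
  expect_equal(average_precision(dets, gts)$ap, ap1)
})

test_that("identity predictions give mAP 1 and per-class accuracy 1", {
  recs <- random_records(30, seed = 17)
  preds <- unique(recs[, c("video_id", "timestamp_s", "x1", "y1", "x2", "y2")])
  C <- 5
  for (ci in seq_len(C)) preds[[paste0("score_", ci)]] <- 0
  for (i in seq_len(nrow(preds))) {
    acts <- recs$action_id[recs$video_id == preds$video_id[i] &
                             recs$timestamp_s == preds$timestamp_s[i]]
    preds[i, paste0("score_", acts)] <- 1
  }
  s <- evaluate_predictions(preds, recs)
  expect_equal(s$mAP, 1)
  expect_true(all(s$per_class$accuracy == 1))
  expect_true(all(s$per_class$AP[s$per_class$support > 0] == 1))
})

test_that("empty predictions give zero AP and dropping one class only
           zeroes that class", {
  recs <- random_records(20, seed = 23)
  preds <- unique(recs[, c("video_id", "timestamp_s", "x1", "y1", "x2", "y2")])
  for (ci in 1:5) preds[[paste0("score_", ci)]] <- 0
  for (i in seq_len(nrow(preds))) {
    acts <- recs$action_id[recs$video_id == preds$video_id[i] &
                             recs$timestamp_s == preds$timestamp_s[i]]
    preds[i, paste0("score_", acts)] <- 1
  }
  full <- evaluate_predictions(preds, recs)
  drop_cl <- recs$action_id[1]
  # long format with the dropped class's prediction rows removed entirely
  long <- do.call(rbind, lapply(1:5, function(ci) {
    df <- preds[, c("video_id", "timestamp_s", "x1", "y1", "x2", "y2")]
    df$action_id <- ci
    df$score <- preds[[paste0("score_", ci)]]
    df
  }))
  part <- evaluate_predictions(long[long$action_id != drop_cl, ], recs)
  expect_equal(part$per_class$AP[drop_cl], 0)
  keep <- setdiff(which(full$per_class$support > 0), drop_cl)
  expect_equal(part$per_class$AP[keep], full$per_class$AP[keep])
  expect_error(evaluate_predictions(preds, recs[0, ]), "empty ground truth")
})

test_that("randomized scores drive per-class AP to class prevalence", {
  # balanced three-posture GT: 60 entity-seconds, 20 per posture
  rows <- lapply(0:59, function(s) {
    data.frame(video_id = "v", timestamp_s = s, x1 = 0.2, y1 = 0.2, x2 = 0.7,
               y2 = 0.7, action_id = (s %% 3) + 1L, entity_id = 0L)
  })
  gt <- validate_ava_records(do.call(rbind, rows))
  preds0 <- unique(gt[, c("video_id", "timestamp_s", "x1", "y1", "x2", "y2")])
  set.seed(99)
  aps <- replicate(100, {
    preds <- preds0
    for (ci in 1:5) preds[[paste0("score_", ci)]] <- runif(nrow(preds))
    evaluate_predictions(preds, gt)$mAP
  })
  # permutation-null oracle: expected AP of a random ranking of 60
  # candidates holding 20 positives, via independent brute-force integration
  truth <- rep(c(TRUE, FALSE), c(20, 40))
  null_aps <- replicate(200, brute_force_ap(sample(truth), 20))
  prevalence <- 20 / 60
  tol <- 3 * sqrt(stats::var(aps) / length(aps) +
                    stats::var(null_aps) / length(null_aps))
  expect_lt(abs(mean(aps) - mean(null_aps)), max(tol, 0.01))
  # and the null sits at the class prevalence up to finite-sample bias
  expect_lt(abs(mean(null_aps) - prevalence), 0.1)
})
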