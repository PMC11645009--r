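# Desk-scale training / evaluation harness: renders a synthetic corpus into
# network-ready clip samples, trains the recognizer, and runs the loss /
# attention-placement comparison grid.

#' Render a corpus into network-ready clip samples
#'
#' Renders each synthetic video in memory, builds one sample per annotated
#' second (clip-pair tensors at the network input size, the annotated box,
#' and the multi-hot label vector), and splits samples into train and test
#' with a seeded shuffle. Videos are processed one at a time so only the
#' downsampled tensors are kept.
#'
#' @param n_videos,duration_s Corpus size.
#' @param render_cfg A [render_config()].
#' @param net_cfg A [net_config()] (input size, window arithmetic).
#' @param seed Integer seed (scripts, rendering, split).
#' @param split Train/test ratio passed to [split_dataset()].
#' @param stratified Exact default composition (default) or i.i.d.
#' @param labels Label map.
#' @return A `recognition_dataset`: list with `train`, `test` (sample lists;
#'   each sample has `slow`, `fast`, `box`, `y`, `video_id`, `timestamp_s`),
#'   `records` (all ground truth), `test_records`, `labels`.
#' @export
recognition_dataset <- function(n_videos = 32, duration_s = 4,
                                render_cfg = render_config(),
                                net_cfg = net_config(), seed = 1,
                                split = c(0.8, 0.2), stratified = TRUE,
                                labels = default_label_map()) {
  combos <- corpus_combos(n_videos, stratified, seed)
  C <- nrow(labels)
  samples <- list(); rec_list <- list(); k <- 0
  for (i in seq_len(n_videos)) {
    vid <- sprintf("v%03d", i - 1)
    vseed <- derive_seed(seed, paste0("video_", vid))
    script <- scene_script_for_combo(combos[i], vseed, duration_s,
                                     video_id = vid)
    rv <- render_video(script, render_cfg, labels)
    for (s in 0:(duration_s - 1)) {
      grp <- rv$records[rv$records$timestamp_s == s, , drop = FALSE]
      clip <- make_clip_pair(s, render_cfg$fps,
                             window_len = net_cfg$window_len,
                             s_slow = net_cfg$s_slow,
                             s_fast = net_cfg$s_fast)
      tens <- clip_tensor(rv$frames, clip, size = net_cfg$input_size)
      y <- integer(C); y[grp$action_id] <- 1L
      k <- k + 1
      samples[[k]] <- list(slow = tens$slow, fast = tens$fast,
                           box = as.numeric(grp[1, c("x1", "y1", "x2", "y2")]),
                           y = y, video_id = vid, timestamp_s = s)
    }
    rec_list[[i]] <- rv$records
    rm(rv); gc(verbose = FALSE)
  }
  records <- do.call(rbind, rec_list)
  sp <- split_dataset(seq_along(samples), ratio = split,
                      seed = derive_seed(seed, "dataset_split"))
  test_keys <- vapply(samples[sp$test], function(s)
    paste(s$video_id, s$timestamp_s), character(1))
  key_all <- paste(records$video_id, records$timestamp_s)
  structure(list(train = samples[sp$train], test = samples[sp$test],
                 records = records,
                 test_records = records[key_all %in% test_keys, , drop = FALSE],
                 labels = labels, seed = seed),
            class = "recognition_dataset")
}

#' Multi-hot label matrix of a sample list
#'
#' @param samples Sample list from [recognition_dataset()].
#' @return N x C binary matrix, one row per sample.
#' @export
samples_labels <- function(samples) do.call(rbind, lapply(samples, `[[`, "y"))

#' Score a sample list with a trained model
#'
#' @param model Trained `sefast_model`.
#' @param samples Sample list from [recognition_dataset()].
#' @param boxes Optional list of replacement boxes (e.g. detector output),
#'   one per sample; defaults to each sample's annotated box.
#' @return Score matrix, one row per sample, one column per class.
#' @export
score_samples <- function(model, samples, boxes = NULL) {
  t(vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    b <- if (is.null(boxes)) s$box else boxes[[i]]
    as.vector(predict_sefast(model, s$slow, s$fast, matrix(b, 1)))
  }, numeric(model$cfg$num_classes)))
}

#' Threshold-based per-class classifier metrics
#'
#' Decision at score >= 0.5 against multi-hot truth; reports per-class
#' precision, recall, accuracy, support, and the rank-based per-class AP of
#' the score ordering (binary AP, every instance a candidate).
#'
#' @param scores N x C score matrix.
#' @param y N x C binary truth matrix.
#' @param labels Label map.
#' @return data.frame, one row per class.
#' @export
classifier_metrics <- function(scores, y, labels = default_label_map()) {
  C <- ncol(y)
  out <- data.frame(id = labels$id, name = labels$name, precision = NA_real_,
                    recall = NA_real_, accuracy = NA_real_, AP = NA_real_,
                    support = colSums(y))
  for (c in seq_len(C)) {
    pred <- scores[, c] >= 0.5
    tp <- sum(pred & y[, c] == 1); fp <- sum(pred & y[, c] == 0)
    fn <- sum(!pred & y[, c] == 1)
    pr <- precision_recall(tp, fp, fn)
    out$precision[c] <- pr$precision
    out$recall[c] <- pr$recall
    out$accuracy[c] <- mean(pred == (y[, c] == 1))
    out$AP[c] <- binary_ap(scores[, c], y[, c])
  }
  out
}

# rank-based binary average precision (ties by index)
binary_ap <- function(score, truth) {
  n_pos <- sum(truth == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(-score, seq_along(score))
  tr <- truth[ord] == 1
  prec <- cumsum(tr) / seq_along(tr)
  sum(prec[tr]) / n_pos
}

#' Predict on a dataset's test split through a detection stage and evaluate
#'
#' Runs the detector on the test ground truth, scores every detection box
#' with the recognizer (using the clip of its video-second), and evaluates
#' mAP at the given IoU threshold against the test annotations.
#'
#' @param model Trained `sefast_model`.
#' @param dataset A `recognition_dataset`.
#' @param detector A [detector_spec()] (default: exact oracle).
#' @param iou_thr IoU threshold.
#' @return List with `summary` (an `eval_summary`), `predictions`, and
#'   `detections`.
#' @export
evaluate_pipeline <- function(model, dataset, detector = detector_spec(),
                              iou_thr = 0.5) {
  dets <- if (detector$kind == "imported") read_detection_json(detector$path)
          else oracle_detect(dataset$test_records, detector)
  skey <- vapply(dataset$test, function(s) paste(s$video_id, s$timestamp_s),
                 character(1))
  preds <- list()
  for (i in seq_len(nrow(dets))) {
    j <- match(paste(dets$video_id[i], dets$timestamp_s[i]), skey)
    if (is.na(j)) next
    s <- dataset$test[[j]]
    box <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
    sc <- as.vector(predict_sefast(model, s$slow, s$fast, matrix(box, 1)))
    df <- data.frame(video_id = dets$video_id[i],
                     timestamp_s = dets$timestamp_s[i],
                     x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4])
    df[paste0("score_", seq_along(sc))] <- as.list(sc)
    preds[[length(preds) + 1]] <- df
  }
  predictions <- do.call(rbind, preds)
  summary <- evaluate_predictions(predictions, dataset$test_records,
                                  dataset$labels, iou_thr)
  list(summary = summary, predictions = predictions, detections = dets)
}

#' Loss / attention-placement comparison grid
#'
#' Trains the recognizer once per (SE placement, loss kind, focal exponent,
#' seed) cell on the dataset's train split and reports per-class metrics on
#' the test split — both thresholded accuracy/recall and rank-based AP, since
#' grid comparisons are read with either metric. Class weights for the `cw`
#' variants are computed from the train split's label counts. Seeded and
#' deterministic per cell; infeasible cells are skipped with a log entry.
#'
#' @param dataset A `recognition_dataset`.
#' @param net_cfg Base [net_config()]; the placement field is overridden per
#'   cell.
#' @param losses Character vector of loss kinds.
#' @param r_values Focal exponents to sweep (ignored for non-focal losses).
#' @param seeds Integer vector of training seeds.
#' @param placements SE placements to sweep (default just the base config's).
#' @param epochs,lr Training hyperparameters.
#' @param verbose Log progress.
#' @return data.frame, one row per (placement, loss, r, seed, class).
#' @export
compare_losses <- function(dataset, net_cfg = net_config(),
                           losses = c("bce_f", "cw_f"), r_values = 2,
                           seeds = 1, placements = net_cfg$se_placement,
                           epochs = 8, lr = 4e-3, verbose = FALSE) {
  y_train <- samples_labels(dataset$train)
  y_test <- samples_labels(dataset$test)
  counts <- colSums(y_train)
  rows <- list()
  for (pl in placements) for (lk in losses) for (r in r_values)
    for (sd in seeds) {
      if (lk %in% c("cw", "cw_f") && any(counts == 0)) {
        sf_log("skipping cell ", pl, "/", lk, ": a class has zero count",
               level = "WARN")
        next
      }
      w <- if (lk %in% c("cw", "cw_f"))
        compute_class_weights(pmax(counts, 1)) else NULL
      r_eff <- if (lk %in% c("bce_f", "cw_f")) r else NA
      loss <- if (is.na(r_eff)) make_loss(lk, weights = w)
              else make_loss(lk, weights = w, r = r_eff)
      cfg <- net_cfg; cfg$se_placement <- pl
      if (verbose) sf_log("training cell ", pl, "/", lk, "/r=", r_eff,
                          "/seed=", sd)
      model <- train_sefast(dataset$train, cfg, loss, epochs = epochs,
                            lr = lr, seed = sd, verbose = FALSE)
      scores <- score_samples(model, dataset$test)
      m <- classifier_metrics(scores, y_test, dataset$labels)
      m$se_placement <- pl; m$loss <- lk; m$r <- r_eff; m$seed <- sd
      rows[[length(rows) + 1]] <- m
    }
  if (length(rows) == 0L) stop("no feasible grid cell")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
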