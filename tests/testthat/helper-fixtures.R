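# Shared fixtures. Expensive objects (the rendered study-scale corpus and the
# trained models) are built once per session and cached; everything is seeded
# so results are identical across runs.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# the loss-comparison corpus: 32 videos stratified to the default composition,
# desk-scale render, 4 s per video
fix_dataset <- function() {
  fixture("dataset", function() {
    recognition_dataset(n_videos = 32, duration_s = 4,
                        render_cfg = render_config(seed = 1),
                        net_cfg = net_config(), seed = 1)
  })
}

# trained recognizer for a given loss kind and seed (SE at the slow-path end)
fix_model <- function(loss_kind, seed) {
  fixture(paste0("model_", loss_kind, "_", seed), function() {
    ds <- fix_dataset()
    counts <- colSums(samples_labels(ds$train))
    w <- if (loss_kind %in% c("cw", "cw_f"))
      compute_class_weights(counts) else NULL
    loss <- make_loss(loss_kind, weights = w, r = 2)
    train_sefast(ds$train, net_config(), loss, epochs = 8, lr = 4e-3,
                 seed = seed)
  })
}

# a tiny corpus written to disk (frames, csv, json, manifest)
fix_corpus_dir <- function() {
  fixture("corpus_dir", function() {
    dir <- file.path(tempdir(), "stallfast_corpus_fixture")
    build_corpus(dir, n_videos = 2, duration_s = 2,
                 cfg = render_config(width = 64, height = 64, fps = 10,
                                     seed = 4),
                 seed = 4, overwrite = TRUE)
  })
}

# random valid annotation set: n entity-seconds with legal label combinations
random_records <- function(n, seed = 1, labels = default_label_map()) {
  set.seed(seed)
  comp <- default_corpus_composition()
  rows <- list()
  for (i in seq_len(n)) {
    x1 <- runif(1, 0, 0.6); y1 <- runif(1, 0, 0.6)
    x2 <- x1 + runif(1, 0.05, 0.39); y2 <- y1 + runif(1, 0.05, 0.39)
    combo <- comp[sample(nrow(comp), 1, prob = comp$n_videos), ]
    acts <- label_id(labels, combo$posture)
    if (!is.na(combo$behavior)) acts <- c(acts, label_id(labels, combo$behavior))
    rows[[i]] <- data.frame(video_id = sprintf("v%02d", sample(3, 1)),
                            timestamp_s = i, x1 = round(x1, 3),
                            y1 = round(y1, 3), x2 = round(x2, 3),
                            y2 = round(y2, 3), action_id = acts,
                            entity_id = 0L)
  }
  validate_ava_records(do.call(rbind, rows), labels)
}

# brute-force PR-curve integration used as the AP oracle: recompute
# precision/recall at every prefix from scratch and integrate against the
# right-side precision envelope found by explicit scanning
brute_force_ap <- function(is_tp, n_gt) {
  n <- length(is_tp)
  if (n == 0 || n_gt == 0) return(0)
  prec <- rec <- numeric(n)
  for (k in seq_len(n)) {
    tp <- sum(is_tp[seq_len(k)])
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  ap <- 0
  r_prev <- 0
  for (k in seq_len(n)) {
    env <- max(prec[k:n])
    ap <- ap + (rec[k] - r_prev) * env
    r_prev <- rec[k]
  }
  ap
}
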