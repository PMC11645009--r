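test_that("default composition mirrors the study's combination counts", {
  comp <- default_corpus_composition()
  expect_equal(nrow(comp), 7)
  expect_equal(sum(comp$n_videos), 32)
  expect_equal(comp$n_videos[comp$combo == "Standing+Eating"], 11L)
  # no illegal combination appears (Eating only with Standing)
  expect_false(any(comp$behavior == "Eating" & comp$posture != "Standing",
                   na.rm = TRUE))
})

test_that("scene-script sampling is seeded and rejects illegal mass", {
  s1 <- sample_scene_script(42, 10)
  s2 <- sample_scene_script(42, 10)
  expect_identical(s1, s2)
  s3 <- sample_scene_script(43, 10)
  expect_false(identical(s1$geometry, s3$geometry))
  expect_error(
    sample_scene_script(1, 10, combo_probs = c("Lateral recumbency+Eating" = 1)),
    "illegal"
  )
  expect_error(
    sample_scene_script(1, 10,
                        combo_probs = c("Standing" = 0.4, "Standing+Eating" = 0.4)),
    "sum to 1"
  )
})

test_that("sampled combination frequencies match the default distribution", {
  comp <- default_corpus_composition()
  sc <- sample_scene_script(7, 12000, n_segments = 12000L)
  combo <- ifelse(is.na(sc$states$behavior), sc$states$posture,
                  paste(sc$states$posture, sc$states$behavior, sep = "+"))
  n <- nrow(sc$states)
  for (i in seq_len(nrow(comp))) {
    p <- comp$n_videos[i] / 32
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(combo == comp$combo[i]) - p), 3 * se + 1e-9)
  }
  # Standing+Eating carries the largest share, 11/32
  expect_equal(comp$n_videos[comp$combo == "Standing+Eating"] / 32, 11 / 32)
})

test_that("rendering produces duration*fps frames and one posture per second", {
  cfg <- render_config(width = 96, height = 64, fps = 5, seed = 2)
  sc <- sample_scene_script(3, 4, video_id = "v7")
  rv <- render_video(sc, cfg)
  expect_length(rv$frames, 4 * 5)
  expect_equal(dim(rv$frames[[1]]), c(64, 96, 3))
  lm <- default_label_map()
  for (s in 0:3) {
    acts <- rv$records$action_id[rv$records$timestamp_s == s]
    expect_equal(sum(acts %in% posture_ids(lm)), 1)
  }
  # determinism
  rv2 <- render_video(sample_scene_script(3, 4, video_id = "v7"), cfg)
  expect_identical(rv$frames[[7]], rv2$frames[[7]])
  expect_equal(as.data.frame(rv$records), as.data.frame(rv2$records))
})

test_that("annotated boxes coincide with the animal pixel-mask extent", {
  cfg <- render_config(width = 128, height = 72, fps = 4, seed = 5)
  for (combo in c("Standing+Eating", "Sternal recumbency+Sleeping",
                  "Lateral recumbency")) {
    sc <- scene_script_for_combo(combo, 11, 2)
    rv <- render_video(sc, cfg, keep_masks = TRUE)
    for (f in seq_along(rv$frames)) {
      mask <- rv$masks[[f]]
      rows <- range(which(rowSums(mask) > 0))
      cols <- range(which(colSums(mask) > 0))
      oracle_box <- c((cols[1] - 1) / ncol(mask), (rows[1] - 1) / nrow(mask),
                      cols[2] / ncol(mask), rows[2] / nrow(mask))
      expect_gte(box_iou(rv$boxes[f, ], oracle_box), 0.9)
    }
  }
})

test_that("no illegal combination ever appears in generated annotations", {
  ds <- fix_dataset()
  expect_s3_class(validate_ava_records(ds$records), "ava_records")
  # scan: Eating rows always accompanied by Standing at the same second
  eat <- ds$records[ds$records$action_id == 4, ]
  for (i in seq_len(nrow(eat))) {
    acts <- ds$records$action_id[ds$records$video_id == eat$video_id[i] &
                                   ds$records$timestamp_s == eat$timestamp_s[i]]
    expect_true(1 %in% acts)
  }
})

test_that("a stratified 32-video corpus reproduces the composition exactly", {
  combos <- stallfast:::corpus_combos(32, stratified = TRUE, seed = 1)
  comp <- default_corpus_composition()
  expect_equal(as.vector(table(factor(combos, levels = comp$combo))),
               comp$n_videos)
  # and the rendered fixture corpus has those per-video combinations
  ds <- fix_dataset()
  per_video <- unique(ds$records[, c("video_id", "action_id")])
  postures <- vapply(split(per_video$action_id, per_video$video_id),
                     function(a) min(a), numeric(1))
  expect_equal(as.vector(table(factor(postures, levels = 1:3))),
               c(18, 7, 7))  # Standing 3+11+4, recumbencies 4+3 and 3+4
})

test_that("postures are linearly separable from mask shape features", {
  skip_if_not_installed("MASS")
  ds <- fix_dataset()
  recs <- ds$records[ds$records$action_id %in% 1:3, ]
  feats <- data.frame(height = recs$y2 - recs$y1,
                      aspect = (recs$y2 - recs$y1) / (recs$x2 - recs$x1),
                      posture = factor(recs$action_id))
  fit <- MASS::lda(posture ~ height + aspect, data = feats)
  pred <- stats::predict(fit, feats)$class
  expect_equal(mean(pred == feats$posture), 1)
})

test_that("corpus build writes a consumable, reproducible directory", {
  corpus <- fix_corpus_dir()
  expect_true(file.exists(file.path(corpus$dir, "ava.csv")))
  expect_true(file.exists(file.path(corpus$dir, "manifest.yaml")))
  expect_length(list.files(file.path(corpus$dir, "v000"),
                           pattern = "\\.jpg$"), 2 * 10)
  back <- read_ava_csv(file.path(corpus$dir, "ava.csv"))
  expect_equal(length(unique(paste(back$video_id, back$timestamp_s))), 2 * 2)
  expect_gte(nrow(back), 4); expect_lte(nrow(back), 8)
  expect_equal(sort(unique(back$video_id)), c("v000", "v001"))

  # refusing to clobber
  expect_error(build_corpus(corpus$dir, n_videos = 1, duration_s = 1),
               "not empty")

  # byte-identical annotations for identical seeds
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- render_config(width = 64, height = 64, fps = 4, seed = 9)
  build_corpus(d1, n_videos = 2, duration_s = 2, cfg = cfg, seed = 9,
               write_frames = FALSE, overwrite = TRUE)
  build_corpus(d2, n_videos = 2, duration_s = 2, cfg = cfg, seed = 9,
               write_frames = FALSE, overwrite = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, "ava.csv"))),
                   unname(tools::md5sum(file.path(d2, "ava.csv"))))

  # single-video corpus is valid
  d3 <- withr::local_tempdir()
  c3 <- build_corpus(d3, n_videos = 1, duration_s = 2, cfg = cfg,
                     write_frames = FALSE, overwrite = TRUE)
  expect_gte(nrow(c3$records), 2)
})
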