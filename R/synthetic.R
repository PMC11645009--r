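# Seeded synthetic stall scenes with exact ground truth.
#
# One animal per stall, rendered as a geometric horse surrogate whose
# silhouette separates the three postures (tall standing shape with legs;
# chest-down compact shape; flat lateral shape) and whose dynamics carry the
# behavior cues: eating adds a lowered, bobbing head; awake animals show a
# small body sway and a gentle brightness flutter while sleeping animals are
# static. Boxes are computed from the rendered animal mask, so ground truth is
# exact by construction.

#' The default label-combination composition of a 32-video corpus
#'
#' The seven legal posture/behavior combinations with their default video
#' counts (out of 32) used by stratified corpus generation, and the expected
#' frame counts per combination for 60 s videos sampled at 1 + 30 frames per
#' second.
#'
#' @param duration_s Video length in seconds (default 60).
#' @param rates Frame-extraction rates in frames per second (default `c(1, 30)`).
#' @return data.frame with columns `posture`, `behavior` (NA for
#'   posture-only), `combo`, `n_videos`, `n_frames`.
#' @export
default_corpus_composition <- function(duration_s = 60, rates = c(1, 30)) {
  df <- data.frame(
    posture = c("Standing", "Standing", "Standing",
                "Sternal recumbency", "Sternal recumbency",
                "Lateral recumbency", "Lateral recumbency"),
    behavior = c(NA, "Eating", "Sleeping", NA, "Sleeping", NA, "Sleeping"),
    n_videos = c(3L, 11L, 4L, 4L, 3L, 3L, 4L),
    stringsAsFactors = FALSE
  )
  df$combo <- ifelse(is.na(df$behavior), df$posture,
                     paste(df$posture, df$behavior, sep = "+"))
  df$n_frames <- df$n_videos * duration_s * sum(rates)
  df[, c("posture", "behavior", "combo", "n_videos", "n_frames")]
}

#' Rendering configuration for synthetic stall videos
#'
#' Defaults are desk-scale (256 x 144 at 10 fps, preserving the 16:9 aspect
#' of the 1920 x 1080 / 30 fps source footage the generator emulates); pass
#' `width = 1920, height = 1080, fps = 30` for full-scale frames.
#'
#' @param width,height Frame size in pixels (>= 64).
#' @param fps Frames per second (>= 1).
#' @param noise_sd Gaussian pixel noise, in 8-bit gray levels.
#' @param seed Integer seed for all render randomness.
#' @return A `render_config` list.
#' @export
render_config <- function(width = 256, height = 144, fps = 10,
                          noise_sd = 2, seed = 1) {
  stopifnot(width >= 64, height >= 64, fps >= 1, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = as.integer(fps), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "render_config")
}

legal_combo <- function(posture, behavior) {
  comp <- default_corpus_composition()
  any(comp$posture == posture &
        (is.na(comp$behavior) & is.na(behavior) |
           !is.na(comp$behavior) & !is.na(behavior) &
           comp$behavior == behavior))
}

#' Sample a scene script
#'
#' Draws the posture/behavior combination(s) of one synthetic video from a
#' distribution over the seven legal combinations, plus the stall geometry
#' nuisance parameters (animal base position and color, texture seed, motion
#' phases). Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param duration_s Total video length in seconds.
#' @param combo_probs Named numeric vector of probabilities; names must be
#'   combos as in [default_corpus_composition()]`$combo`. Default: proportional
#'   to the default composition's video counts. Mass on an unknown or illegal
#'   combination is a configuration error.
#' @param n_segments Number of constant-state segments (default 1).
#' @param video_id Identifier stored in the script.
#' @return A `scene_script` list with `states` (posture, behavior, duration_s
#'   per segment) and `geometry`.
#' @export
sample_scene_script <- function(seed, duration_s,
                                combo_probs = NULL, n_segments = 1L,
                                video_id = "v000") {
  comp <- default_corpus_composition()
  if (is.null(combo_probs)) {
    combo_probs <- stats::setNames(comp$n_videos / sum(comp$n_videos),
                                   comp$combo)
  }
  if (is.null(names(combo_probs)) || any(!nzchar(names(combo_probs))))
    stop("combo_probs must be named by combination")
  bad <- setdiff(names(combo_probs)[combo_probs > 0], comp$combo)
  if (length(bad) > 0L)
    stop("configuration error: probability mass on illegal combination(s): ",
         paste(bad, collapse = ", "))
  if (abs(sum(combo_probs) - 1) > 1e-8)
    stop("combo_probs must sum to 1")
  stopifnot(duration_s >= 1, n_segments >= 1, n_segments <= duration_s)

  probs <- stats::setNames(rep(0, nrow(comp)), comp$combo)
  probs[names(combo_probs)] <- combo_probs

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "scene_script"))

  picks <- sample.int(nrow(comp), n_segments, replace = TRUE, prob = probs)
  base_d <- duration_s %/% n_segments
  durs <- rep(base_d, n_segments)
  durs[n_segments] <- durs[n_segments] + duration_s - sum(durs)
  states <- data.frame(posture = comp$posture[picks],
                       behavior = comp$behavior[picks],
                       duration_s = durs, stringsAsFactors = FALSE)
  geometry <- list(
    base_x = stats::runif(1, 0.35, 0.60),
    animal_rgb = c(stats::runif(1, 0.25, 0.45), stats::runif(1, 0.16, 0.30),
                   stats::runif(1, 0.08, 0.18)) * 255,
    texture_seed = derive_seed(seed, "texture"),
    phase = stats::runif(3, 0, 2 * pi),
    lum_phase = stats::runif(1, 0, 2 * pi)
  )
  structure(list(video_id = video_id, states = states, geometry = geometry,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "scene_script")
}

#' Force a scene script to a fixed combination
#'
#' Convenience used by stratified corpus generation: same geometry sampling as
#' [sample_scene_script()] but with the posture/behavior combination fixed.
#'
#' @inheritParams sample_scene_script
#' @param combo A combo string from [default_corpus_composition()]`$combo`.
#' @return A `scene_script`.
#' @export
scene_script_for_combo <- function(combo, seed, duration_s,
                                   video_id = "v000") {
  comp <- default_corpus_composition()
  i <- match(combo, comp$combo)
  if (is.na(i)) stop("configuration error: illegal combination: ", combo)
  sc <- sample_scene_script(seed, duration_s,
                            combo_probs = stats::setNames(1, combo),
                            video_id = video_id)
  sc$states$posture <- comp$posture[i]
  sc$states$behavior <- comp$behavior[i]
  sc
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- rendering ------------------------------------------------------------

# smooth seeded background texture, H x W in gray levels
make_background <- function(H, W, texture_seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(texture_seed)
  gh <- 6; gw <- 9
  coarse <- matrix(stats::rnorm(gh * gw, 0, 10), gh, gw)
  tex <- resize_image(coarse, H, W)
  base <- 170 + tex
  grad <- matrix(seq(-8, 8, length.out = H), H, W)  # dimmer floor
  base + grad
}

# draw one frame; returns list(img = HxWx3 gray levels, mask = HxW logical)
render_frame <- function(t, state, geom, H, W) {
  u <- matrix(seq(0.5 / W, 1 - 0.5 / W, length.out = W), H, W, byrow = TRUE)
  v <- matrix(seq(0.5 / H, 1 - 0.5 / H, length.out = H), H, W)
  sleeping <- !is.na(state$behavior) && state$behavior == "Sleeping"
  eating <- !is.na(state$behavior) && state$behavior == "Eating"
  sway <- if (sleeping) 0 else 0.010 * sin(2 * pi * 0.5 * t + geom$phase[1])
  bx <- geom$base_x + sway

  ell <- function(cx, cy, a, b) ((u - cx) / a)^2 + ((v - cy) / b)^2 <= 1
  rect <- function(x1, x2, y1, y2) u >= x1 & u <= x2 & v >= y1 & v <= y2

  mask <- matrix(FALSE, H, W)
  if (state$posture == "Standing") {
    mask <- mask | ell(bx, 0.50, 0.145, 0.105)
    for (dx in c(-0.10, -0.035, 0.035, 0.10))
      mask <- mask | rect(bx + dx - 0.010, bx + dx + 0.010, 0.52, 0.82)
    if (eating) {
      bob <- 0.020 * sin(2 * pi * 1.2 * t + geom$phase[2])
      hx <- bx + 0.205; hy <- 0.76 + bob
      mask <- mask | ell(bx + 0.16, 0.62, 0.035, 0.10)   # lowered neck
      mask <- mask | ell(hx, hy, 0.050, 0.038)           # head at the ground
    } else {
      nod <- if (sleeping) 0 else 0.008 * sin(2 * pi * 0.8 * t + geom$phase[2])
      mask <- mask | ell(bx + 0.155, 0.40, 0.032, 0.10)  # raised neck
      mask <- mask | ell(bx + 0.19, 0.31 + nod, 0.050, 0.038)
    }
  } else if (state$posture == "Sternal recumbency") {
    mask <- mask | ell(bx, 0.72, 0.165, 0.085)
    mask <- mask | ell(bx + 0.14, 0.60, 0.030, 0.075)    # raised neck
    mask <- mask | ell(bx + 0.165, 0.545, 0.045, 0.035)  # head up
    mask <- mask | ell(bx - 0.05, 0.795, 0.12, 0.022)    # folded legs
  } else {  # Lateral recumbency
    mask <- mask | ell(bx, 0.785, 0.215, 0.052)
    mask <- mask | ell(bx + 0.245, 0.79, 0.048, 0.032)   # head on the ground
    for (dy in c(-0.012, 0.012))
      mask <- mask | rect(bx - 0.32, bx - 0.19, 0.785 + dy - 0.008,
                          0.785 + dy + 0.008)            # outstretched legs
  }
  flutter <- if (sleeping) 1 else 1 + 0.12 * sin(2 * pi * 2.5 * t + geom$phase[3])
  list(mask = mask, flutter = flutter)
}

mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) stop("empty animal mask")
  H <- nrow(mask); W <- ncol(mask)
  c(x1 = (min(cols) - 1) / W, y1 = (min(rows) - 1) / H,
    x2 = max(cols) / W, y2 = max(rows) / H)
}

#' Render a synthetic stall video with ground-truth annotations
#'
#' Produces `duration_s * fps` frames (H x W x 3 arrays in 8-bit gray levels)
#' plus one group of AVA-style annotation rows per second for the single
#' animal (entity 0), with the box computed from the rendered animal mask of
#' that second's first frame. Deterministic given the script and config seeds.
#'
#' @param script A `scene_script`.
#' @param cfg A `render_config`.
#' @param labels Label map for action ids.
#' @param keep_masks Also return the per-frame animal masks (for testing).
#' @return List with `frames` (list of arrays), `records` (`ava_records`),
#'   `boxes` (per-frame matrix), and optionally `masks`.
#' @export
render_video <- function(script, cfg = render_config(),
                         labels = default_label_map(), keep_masks = FALSE) {
  stopifnot(inherits(script, "scene_script"), inherits(cfg, "render_config"))
  H <- cfg$height; W <- cfg$width; fps <- cfg$fps
  geom <- script$geometry
  bg <- make_background(H, W, geom$texture_seed)
  n_frames <- script$duration_s * fps
  state_of_second <- rep(seq_len(nrow(script$states)),
                         times = script$states$duration_s)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed + script$seed, "render_noise"))

  tex_mod <- 1 + 0.06 * sin(outer(seq_len(H), rep(1, W)) * 0.7) *
    sin(outer(rep(1, H), seq_len(W)) * 0.7)

  frames <- vector("list", n_frames)
  masks <- if (keep_masks) vector("list", n_frames) else NULL
  boxes <- matrix(NA_real_, n_frames, 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  for (f in seq_len(n_frames)) {
    t <- (f - 1) / fps
    sec <- min(floor(t) + 1, length(state_of_second))
    st <- script$states[state_of_second[sec], ]
    rf <- render_frame(t, st, geom, H, W)
    lum <- 1 + 0.10 * sin(2 * pi * t / max(script$duration_s, 30) +
                            geom$lum_phase)
    img <- array(0, dim = c(H, W, 3))
    body <- tex_mod * rf$flutter
    for (ch in 1:3) {
      plane <- bg * lum
      plane[rf$mask] <- (geom$animal_rgb[ch] * body)[rf$mask]
      img[, , ch] <- plane
    }
    if (cfg$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd), dim(img))
    img[img < 0] <- 0; img[img > 255] <- 255
    frames[[f]] <- img
    boxes[f, ] <- mask_bbox(rf$mask)
    if (keep_masks) masks[[f]] <- rf$mask
  }

  recs <- list()
  for (s in seq_len(script$duration_s)) {
    st <- script$states[state_of_second[s], ]
    f0 <- (s - 1) * fps + 1
    b <- boxes[f0, ]
    acts <- label_id(labels, st$posture)
    if (!is.na(st$behavior)) acts <- c(acts, label_id(labels, st$behavior))
    recs[[s]] <- new_ava_records(script$video_id, s - 1,
                                 b[1], b[2], b[3], b[4], acts, 0L)
  }
  records <- validate_ava_records(do.call(rbind, recs), labels)
  out <- list(frames = frames, records = records, boxes = boxes,
              fps = fps, video_id = script$video_id)
  if (keep_masks) out$masks <- masks
  out
}

#' Build a synthetic corpus on disk
#'
#' Renders `n_videos` stall videos and writes frame images
#' (`{video_id}/{frame:06d}.jpg`), an AVA-style annotation CSV (`ava.csv`), a
#' ground-truth detection JSON (`detections.json`, score 1), and a manifest
#' (`manifest.yaml`) listing the per-video combination. With
#' `stratified = TRUE` (default) the corpus reproduces the default
#' composition's video counts exactly (largest-remainder apportionment for
#' `n_videos != 32`); otherwise combinations are drawn i.i.d.
#'
#' @param out_dir Output directory (must be empty unless `overwrite = TRUE`).
#' @param n_videos,duration_s Corpus size (defaults 32 videos x 60 s).
#' @param cfg A `render_config`.
#' @param seed Integer corpus seed.
#' @param stratified Exact default composition (default) or i.i.d. sampling.
#' @param write_frames Write JPEG frames (disable to materialize only
#'   annotations and manifest).
#' @param overwrite Allow writing into a non-empty directory.
#' @param labels Label map.
#' @return A `stall_corpus` list: `dir`, `manifest`, `records`, `detections`.
#' @export
build_corpus <- function(out_dir, n_videos = 32, duration_s = 60,
                         cfg = render_config(), seed = 1, stratified = TRUE,
                         write_frames = TRUE, overwrite = FALSE,
                         labels = default_label_map()) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  combos <- corpus_combos(n_videos, stratified, seed)
  all_recs <- list(); all_dets <- list(); mani <- list()
  for (i in seq_len(n_videos)) {
    vid <- sprintf("v%03d", i - 1)
    vseed <- derive_seed(seed, paste0("video_", vid))
    script <- scene_script_for_combo(combos[i], vseed, duration_s,
                                     video_id = vid)
    rv <- render_video(script, cfg, labels)
    if (write_frames) {
      vdir <- file.path(out_dir, vid)
      dir.create(vdir, showWarnings = FALSE)
      for (f in seq_along(rv$frames)) {
        EBImage::writeImage(
          EBImage::Image(aperm(rv$frames[[f]], c(2, 1, 3)) / 255,
                         colormode = "Color"),
          file.path(vdir, sprintf("%06d.jpg", f - 1)), quality = 92)
      }
    }
    all_recs[[i]] <- rv$records
    d <- unique(rv$records[, c("video_id", "timestamp_s",
                               "x1", "y1", "x2", "y2")])
    d$score <- 1
    all_dets[[i]] <- d
    mani[[vid]] <- list(combo = combos[i], seed = vseed,
                        duration_s = duration_s, n_frames = length(rv$frames))
  }
  records <- do.call(rbind, all_recs)
  dets <- do.call(rbind, all_dets)
  rownames(dets) <- NULL
  write_ava_csv(records, file.path(out_dir, "ava.csv"), labels)
  write_detection_json(dets, file.path(out_dir, "detections.json"))
  manifest <- list(n_videos = n_videos, duration_s = duration_s, seed = seed,
                   stratified = stratified,
                   render = unclass(cfg), videos = mani)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(list(dir = out_dir, manifest = manifest, records = records,
                 detections = validate_detections(dets)),
            class = "stall_corpus")
}

# per-video combo assignment
corpus_combos <- function(n_videos, stratified, seed) {
  comp <- default_corpus_composition()
  if (!stratified) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, "corpus_combos"))
    return(sample(comp$combo, n_videos, replace = TRUE,
                  prob = comp$n_videos / sum(comp$n_videos)))
  }
  quota <- n_videos * comp$n_videos / sum(comp$n_videos)
  n <- floor(quota)
  rem <- n_videos - sum(n)
  if (rem > 0) {
    extra <- order(quota - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1
  }
  rep(comp$combo, times = n)
}
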