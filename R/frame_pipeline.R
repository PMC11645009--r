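# Dual-rate frame extraction, dataset splitting, clip-window assembly for the
# two pathways, and the three photometric augmentations.

#' Expected frame counts for a dual-rate extraction plan
#'
#' A d-second source sampled at each rate r yields `d * r` frames, so n videos
#' of d seconds at rates `{30, 1}` yield `n * d * 31` frames in total, of
#' which the 1-fps stream carries the annotations.
#'
#' @param duration_s Per-video duration(s) in seconds (vector, recycled).
#' @param rates Frames-per-second extraction rates (default `c(30, 1)`).
#' @param n_videos Number of videos (default `length(duration_s)` if vector,
#'   else 1).
#' @param labeled_rate The rate whose frames receive annotations (default 1).
#' @return List with `per_rate` (named counts summed over videos), `total`,
#'   and `labeled`.
#' @export
extraction_counts <- function(duration_s, rates = c(30, 1), n_videos = NULL,
                              labeled_rate = 1) {
  stopifnot(all(rates >= 1), labeled_rate %in% rates)
  if (is.null(n_videos)) n_videos <- length(duration_s)
  dur <- rep_len(duration_s, n_videos)
  per_rate <- vapply(rates, function(r) sum(floor(dur * r)), numeric(1))
  names(per_rate) <- paste0("fps", rates)
  list(per_rate = per_rate, total = sum(per_rate),
       labeled = per_rate[[paste0("fps", labeled_rate)]])
}

#' Extract per-rate frame lists from a frame-directory source
#'
#' The supported video source is a directory of frame images named
#' `{frame:06d}.jpg` (or `.png`) at a known native rate — the layout written
#' by [build_corpus()]. For each requested rate the native stream is
#' subsampled by taking the first frame of each `native_fps / rate` stride;
#' counts equal `floor(duration * rate)` with any truncated tail dropped.
#'
#' @param source Frame directory of one video.
#' @param rates Frames-per-second rates to extract (each must divide
#'   `native_fps`).
#' @param native_fps The source's frame rate.
#' @param labeled_rate The annotated rate (default 1 when present, else
#'   `min(rates)`).
#' @return List with `counts` (named per rate), `files` (named list of file
#'   vectors per rate), and `labeled_rate`.
#' @export
extract_frames <- function(source, rates = c(30, 1), native_fps = 30,
                           labeled_rate = NULL) {
  if (!dir.exists(source)) stop("unreadable source: ", source)
  files <- sort(list.files(source, pattern = "\\.(jpg|jpeg|png)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frame images in ", source)
  if (any(native_fps %% rates != 0))
    stop("each rate must divide the native fps (", native_fps, ")")
  labeled_rate <- labeled_rate %||% if (1 %in% rates) 1 else min(rates)
  if (!labeled_rate %in% rates) stop("labeled_rate must be one of rates")
  duration <- length(files) %/% native_fps
  out_files <- lapply(rates, function(r) {
    stride <- native_fps %/% r
    idx <- seq(1, duration * native_fps, by = stride)
    files[idx]
  })
  names(out_files) <- paste0("fps", rates)
  counts <- vapply(out_files, length, integer(1))
  list(counts = counts, files = out_files, labeled_rate = labeled_rate)
}

#' Seeded train/test split
#'
#' Shuffles items with a seeded permutation and splits them so that the test
#' set has `round(n * test_frac)` items and the train set takes the remainder
#' (so 1920 items at 8:2 give 1536 / 384). Disjoint and exhaustive.
#'
#' @param items Vector or list to split.
#' @param ratio Length-2 numeric `(train_frac, test_frac)` summing to 1.
#' @param seed Integer seed.
#' @return List with `train` and `test`.
#' @export
split_dataset <- function(items, ratio = c(0.8, 0.2), seed = 1) {
  n <- length(items)
  if (n == 0L) stop("empty input")
  if (length(ratio) != 2L || abs(sum(ratio) - 1) > 1e-8)
    stop("ratio must be (train_frac, test_frac) summing to 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "split_dataset"))
  perm <- sample.int(n)
  n_test <- round(n * ratio[2])
  test_idx <- perm[seq_len(n_test)]
  train_idx <- perm[setdiff(seq_len(n), seq_len(n_test))]
  list(train = items[sort(train_idx)], test = items[sort(test_idx)])
}

#' Dual-rate clip sampling indices for one 64-frame window
#'
#' For a window of `window_len` frames starting at `window_start`, the slow
#' pathway samples every `s_slow`-th frame (`window_len / s_slow` frames) and
#' the fast pathway every `s_fast`-th (`window_len / s_fast` frames); with the
#' default strides 16 / 2 that is 4 slow and 32 fast frames, and the slow
#' indices are a subset of the fast ones. The window is centered on the
#' annotated second's first frame (`center_second * fps`); indices may run
#' past the video edges and are clamped at materialization time
#' ([clip_tensor()]), repeating edge frames.
#'
#' @param center_second Annotated second (0-based).
#' @param fps Frame rate of the frame stream the window indexes into.
#' @param window_len Window length L in frames (default 64).
#' @param s_slow,s_fast Temporal strides (defaults 16 and 2).
#' @return A `clip_pair` list with `window_start`, `window_len`,
#'   `slow_indices`, `fast_indices` (0-based frame indices).
#' @export
make_clip_pair <- function(center_second, fps, window_len = 64,
                           s_slow = 16, s_fast = 2) {
  stopifnot(center_second >= 0, fps >= 1)
  if (window_len %% s_slow != 0 || window_len %% s_fast != 0)
    stop("window_len must be a multiple of both strides")
  center_frame <- center_second * fps
  window_start <- center_frame - window_len %/% 2
  structure(list(
    window_start = window_start, window_len = window_len,
    s_slow = s_slow, s_fast = s_fast,
    slow_indices = window_start + seq(0, window_len - 1, by = s_slow),
    fast_indices = window_start + seq(0, window_len - 1, by = s_fast)
  ), class = "clip_pair")
}

# clamp 0-based clip indices into [0, n_frames-1] (edge repetition)
clamp_indices <- function(idx, n_frames) pmin(pmax(idx, 0L), n_frames - 1L)

#' Materialize a clip pair as network input tensors
#'
#' Gathers and resizes the slow and fast frames of a [make_clip_pair()] window
#' from a list of frames, clamping out-of-range indices to the video edges.
#'
#' @param frames List of H x W x 3 arrays (8-bit gray levels).
#' @param clip A `clip_pair`.
#' @param size Square network input resolution.
#' @return List with `slow` (size x size x N_slow x 3) and `fast`
#'   (size x size x N_fast x 3), values scaled to roughly `[-0.5, 0.5]`.
#' @export
clip_tensor <- function(frames, clip, size = 32) {
  gather <- function(idx0) {
    idx <- clamp_indices(idx0, length(frames)) + 1L
    arr <- array(0, dim = c(size, size, length(idx), 3))
    cache <- new.env()
    for (k in seq_along(idx)) {
      key <- as.character(idx[k])
      small <- if (!is.null(cache[[key]])) cache[[key]] else {
        s <- resize_image(frames[[idx[k]]], size, size) / 255 - 0.5
        cache[[key]] <- s
        s
      }
      arr[, , k, ] <- small
    }
    arr
  }
  list(slow = gather(clip$slow_indices), fast = gather(clip$fast_indices))
}

# ---- photometric augmentations -------------------------------------------

check_image8 <- function(img) {
  if (!is.numeric(img) || is.null(dim(img)) || !length(dim(img)) %in% c(2, 3))
    stop("expected an 8-bit image array (H x W [x C])")
  invisible(img)
}

#' Color jittering
#'
#' Scales brightness and contrast by random factors in
#' `[1 - strength, 1 + strength]` and interpolates saturation likewise
#' (for 3-channel images), deterministic given `seed`. Zero strengths return
#' the input unchanged. Photometric only: annotation geometry is untouched.
#'
#' @param img 8-bit image array (values 0..255), H x W or H x W x 3.
#' @param brightness,contrast,saturation Jitter strengths in `[0, 1]`.
#' @param seed Integer seed.
#' @return Jittered image, same shape and range.
#' @export
color_jitter <- function(img, brightness = 0.2, contrast = 0.2,
                         saturation = 0.2, seed = 1) {
  check_image8(img)
  if (brightness == 0 && contrast == 0 && saturation == 0) return(img)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "color_jitter"))
  fb <- stats::runif(1, 1 - brightness, 1 + brightness)
  fc <- stats::runif(1, 1 - contrast, 1 + contrast)
  fs <- stats::runif(1, 1 - saturation, 1 + saturation)
  out <- img * fb
  m <- mean(out)
  out <- (out - m) * fc + m
  if (length(dim(img)) == 3L && dim(img)[3] == 3L && saturation > 0) {
    gray <- (out[, , 1] + out[, , 2] + out[, , 3]) / 3
    for (ch in 1:3) out[, , ch] <- gray + (out[, , ch] - gray) * fs
  }
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Additive Gaussian pixel noise
#'
#' @param img 8-bit image array.
#' @param sd Noise standard deviation in gray levels; 0 returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @return Noisy image clipped to `[0, 255]`.
#' @export
add_noise <- function(img, sd = 5, seed = 1) {
  check_image8(img)
  if (sd == 0) return(img)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "add_noise"))
  out <- img + array(stats::rnorm(length(img), 0, sd), dim(img))
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based adaptive equalization with clipped histograms, for frames with
#' uneven illumination. Deterministic. Constant (zero-range) images are
#' returned unchanged (their flat histogram is a fixed point of
#' equalization).
#'
#' @param img 8-bit image array.
#' @param clip_limit Contrast clip limit (default 2).
#' @param tile_grid Number of tiles per side (default 8).
#' @return Equalized image, same shape, values in `[0, 255]`.
#' @export
clahe_equalize <- function(img, clip_limit = 2, tile_grid = 8) {
  check_image8(img)
  rng <- range(img)
  if (rng[1] == rng[2]) return(img)
  nd <- length(dim(img))
  x <- if (nd == 2L) t(img) else aperm(img, c(2, 1, 3))  # EBImage is W x H
  eb <- EBImage::Image(x / 255,
                       colormode = if (nd == 2L) "Grayscale" else "Color")
  out <- EBImage::clahe(eb, nx = tile_grid, ny = tile_grid,
                        limit = clip_limit)
  y <- EBImage::imageData(out) * 255
  y <- if (nd == 2L) t(y) else aperm(y, c(2, 1, 3))
  y[y < 0] <- 0; y[y > 255] <- 255
  y
}

#' Apply the augmentation set to a random subset of frames
#'
#' Online training augmentation: a seeded fraction of the given frames is
#' augmented, each with one of the three operations chosen at random.
#'
#' @param frames List of 8-bit frames.
#' @param fraction Fraction of frames to augment (default 0.5).
#' @param seed Integer seed (re-derive per epoch for fresh draws).
#' @param noise_sd Noise strength for the noise op.
#' @return List of frames, augmented in place.
#' @export
augment_frames <- function(frames, fraction = 0.5, seed = 1, noise_sd = 5) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "augment"))
  n <- length(frames)
  pick <- which(stats::runif(n) < fraction)
  ops <- sample(3, length(pick), replace = TRUE)
  subseeds <- sample.int(2^30, length(pick))
  for (k in seq_along(pick)) {
    i <- pick[k]
    frames[[i]] <- switch(ops[k],
      color_jitter(frames[[i]], seed = subseeds[k]),
      add_noise(frames[[i]], sd = noise_sd, seed = subseeds[k]),
      clahe_equalize(frames[[i]]))
  }
  frames
}
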