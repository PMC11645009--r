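# Pluggable animal-detection stage. At desk scale the detector is an oracle
# that emits ground-truth boxes with controlled jitter, dropout and false
# positives; output from any external detector can be imported through the
# detection JSON format instead.

#' Detector specification
#'
#' @param kind `"oracle"` (ground-truth-derived) or `"imported"` (boxes come
#'   from a detection JSON file).
#' @param jitter_sd Gaussian box-corner jitter, normalized units.
#' @param drop_rate Probability of missing a ground-truth instance, in
#'   `[0, 1)`.
#' @param false_positive_rate Expected spurious boxes per annotated second
#'   (>= 0).
#' @param seed Integer seed.
#' @param path Detection JSON path (for `kind = "imported"`).
#' @return A `detector_spec` list.
#' @export
detector_spec <- function(kind = c("oracle", "imported"), jitter_sd = 0,
                          drop_rate = 0, false_positive_rate = 0, seed = 1,
                          path = NULL) {
  kind <- match.arg(kind)
  if (drop_rate < 0 || drop_rate >= 1)
    stop("config error: drop_rate must be in [0, 1)")
  if (jitter_sd < 0 || false_positive_rate < 0)
    stop("config error: rates must be non-negative")
  structure(list(kind = kind, jitter_sd = jitter_sd, drop_rate = drop_rate,
                 false_positive_rate = false_positive_rate,
                 seed = as.integer(seed), path = path),
            class = "detector_spec")
}

#' Oracle detector: ground-truth boxes with controlled corruption
#'
#' Per (video, second, entity) group of the ground truth, with probability
#' `1 - drop_rate` the box is emitted perturbed by Gaussian corner jitter
#' (clipped to `[0, 1]`, geometry kept valid); its score is the
#' `1 - mean |jitter|` heuristic, in (0, 1]. Spurious uniform random boxes
#' are added at `false_positive_rate` per annotated second. Deterministic
#' given the spec's seed.
#'
#' @param gt Validated `ava_records` ground truth.
#' @param spec A [detector_spec()].
#' @return A `detection_records` data.frame.
#' @export
oracle_detect <- function(gt, spec = detector_spec()) {
  stopifnot(inherits(spec, "detector_spec"))
  gt <- validate_ava_records(gt)
  groups <- unique(gt[, c("video_id", "timestamp_s", "entity_id",
                          "x1", "y1", "x2", "y2")])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, "oracle_detect"))
  out <- list(); k <- 0
  for (i in seq_len(nrow(groups))) {
    if (stats::runif(1) < spec$drop_rate) next
    b <- as.numeric(groups[i, c("x1", "y1", "x2", "y2")])
    eps <- stats::rnorm(4, 0, spec$jitter_sd)
    nb <- pmin(pmax(b + eps, 0), 1)
    if (nb[1] >= nb[3]) nb[c(1, 3)] <- sort(c(b[1], b[3]))
    if (nb[2] >= nb[4]) nb[c(2, 4)] <- sort(c(b[2], b[4]))
    k <- k + 1
    out[[k]] <- data.frame(video_id = groups$video_id[i],
                           timestamp_s = groups$timestamp_s[i],
                           x1 = nb[1], y1 = nb[2], x2 = nb[3], y2 = nb[4],
                           score = max(1e-3, min(1, 1 - mean(abs(eps)))),
                           stringsAsFactors = FALSE)
  }
  secs <- unique(groups[, c("video_id", "timestamp_s")])
  if (spec$false_positive_rate > 0) {
    for (i in seq_len(nrow(secs))) {
      n_fp <- stats::rpois(1, spec$false_positive_rate)
      for (j in seq_len(n_fp)) {
        cx <- stats::runif(1, 0.15, 0.85); cy <- stats::runif(1, 0.15, 0.85)
        w2 <- stats::runif(1, 0.03, 0.12); h2 <- stats::runif(1, 0.03, 0.12)
        k <- k + 1
        out[[k]] <- data.frame(video_id = secs$video_id[i],
                               timestamp_s = secs$timestamp_s[i],
                               x1 = cx - w2, y1 = cy - h2,
                               x2 = cx + w2, y2 = cy + h2,
                               score = stats::runif(1, 0.05, 0.5),
                               stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (k == 0) data.frame(video_id = character(),
                               timestamp_s = integer(), x1 = numeric(),
                               y1 = numeric(), x2 = numeric(),
                               y2 = numeric(), score = numeric())
        else do.call(rbind, out)
  rownames(df) <- NULL
  validate_detections(df)
}

#' Match detections to ground-truth entities
#'
#' Greedy score-ordered matching (ties broken by input order) at the given
#' IoU threshold, per (video, second): each detection claims the unclaimed
#' ground-truth entity group with the highest IoU >= `iou_thr`. Matched
#' detections inherit the entity's label set; unmatched detections carry an
#' empty label set; unclaimed ground truth is flagged as missed.
#'
#' @param detections `detection_records`.
#' @param records Validated `ava_records` ground truth.
#' @param labels Label map.
#' @param iou_thr IoU threshold (default 0.5).
#' @return List: `pairs` (data.frame of detections with `matched`,
#'   `entity_id` and a multi-hot label matrix `y` bound as columns
#'   `y_1..y_C`) and `missed` (unclaimed ground-truth groups).
#' @export
attach_detections <- function(detections, records,
                              labels = default_label_map(), iou_thr = 0.5) {
  records <- validate_ava_records(records, labels)
  detections <- validate_detections(detections)
  C <- nrow(labels)
  gkey <- unique(records[, c("video_id", "timestamp_s", "entity_id",
                             "x1", "y1", "x2", "y2")])
  claimed <- rep(FALSE, nrow(gkey))
  n <- nrow(detections)
  matched <- rep(FALSE, n)
  entity <- rep(NA_integer_, n)
  y <- matrix(0L, n, C, dimnames = list(NULL, paste0("y_", seq_len(C))))
  ord <- order(-detections$score, seq_len(n))
  for (i in ord) {
    cand <- which(gkey$video_id == detections$video_id[i] &
                    gkey$timestamp_s == detections$timestamp_s[i] & !claimed)
    if (length(cand) == 0L) next
    ious <- iou_one_many(as.numeric(detections[i, c("x1", "y1", "x2", "y2")]),
                         as.matrix(gkey[cand, c("x1", "y1", "x2", "y2")]))
    j <- which.max(ious)
    if (ious[j] >= iou_thr) {
      claimed[cand[j]] <- TRUE
      matched[i] <- TRUE
      entity[i] <- gkey$entity_id[cand[j]]
      acts <- records$action_id[records$video_id == detections$video_id[i] &
                                  records$timestamp_s == detections$timestamp_s[i] &
                                  records$entity_id == gkey$entity_id[cand[j]]]
      y[i, acts] <- 1L
    }
  }
  pairs <- cbind(detections, matched = matched, entity_id = entity,
                 as.data.frame(y))
  list(pairs = pairs, missed = gkey[!claimed, , drop = FALSE])
}
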