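# AVA-style spatio-temporal annotation records and their CSV serialization.
#
# One row per (video, second, box, action, entity); multiple actions for the
# same entity-second are encoded as multiple rows sharing the same box, as in
# the public AVA convention. Coordinates are normalized corners in [0,1].

#' Validate normalized bounding boxes
#'
#' Boxes are corner-coded `(x1, y1, x2, y2)` in normalized image coordinates,
#' with `0 <= x1 < x2 <= 1`, `0 <= y1 < y2 <= 1` and strictly positive area.
#'
#' @param box Numeric vector of length 4 or a 4-column matrix/data.frame.
#' @param where Optional label used in error messages (e.g. a row number).
#' @return The box, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_box <- function(box, where = NULL) {
  b <- if (is.data.frame(box)) as.matrix(box) else box
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(b) != 4L) stop("a bounding box has 4 coordinates (x1,y1,x2,y2)")
  tag <- if (is.null(where)) "" else paste0(" (", where, ")")
  if (any(!is.finite(b))) stop("non-finite box coordinate", tag)
  if (any(b < 0 | b > 1)) stop("box coordinate outside [0,1]", tag)
  if (any(b[, 1] >= b[, 3]) || any(b[, 2] >= b[, 4]))
    stop("degenerate box: need x1 < x2 and y1 < y2", tag)
  invisible(box)
}

new_ava_records <- function(video_id, timestamp_s, x1, y1, x2, y2,
                            action_id, entity_id) {
  df <- data.frame(video_id = as.character(video_id),
                   timestamp_s = as.integer(timestamp_s),
                   x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                   action_id = as.integer(action_id),
                   entity_id = as.integer(entity_id),
                   stringsAsFactors = FALSE, row.names = NULL)
  class(df) <- c("ava_records", "data.frame")
  df
}

#' Validate a set of AVA-style annotation records
#'
#' Checks box geometry row by row, that every action id exists in the label
#' map, and the posture/behavior combination rules within each
#' (video, second, entity) group: exactly one posture, at most one Sleeping,
#' and Eating only together with Standing.
#'
#' @param records An `ava_records` data.frame.
#' @param labels A `label_map` (default: built-in taxonomy).
#' @return `records` (class `ava_records`), row order preserved.
#' @export
validate_ava_records <- function(records, labels = default_label_map()) {
  labels <- validate_label_map(labels)
  req <- c("video_id", "timestamp_s", "x1", "y1", "x2", "y2",
           "action_id", "entity_id")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  if (nrow(records) == 0L) {
    class(records) <- unique(c("ava_records", class(records)))
    return(records)
  }
  if (any(records$timestamp_s < 0)) stop("negative timestamp_s")
  if (any(records$entity_id < 0)) stop("negative entity_id")
  for (i in seq_len(nrow(records)))
    validate_box(unlist(records[i, c("x1", "y1", "x2", "y2")]),
                 where = paste0("row ", i))
  bad <- !records$action_id %in% labels$id
  if (any(bad))
    stop("unknown action_id in row(s) ", paste(which(bad), collapse = ", "))

  post <- posture_ids(labels)
  id_eat <- label_id(labels, "Eating")
  id_sleep <- label_id(labels, "Sleeping")
  id_stand <- label_id(labels, "Standing")
  key <- paste(records$video_id, records$timestamp_s, records$entity_id,
               sep = "\r")
  for (k in unique(key)) {
    acts <- records$action_id[key == k]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    at <- sprintf("video %s, second %s, entity %s", parts[1], parts[2], parts[3])
    if (sum(acts %in% post) != 1L)
      stop("combination error: need exactly one posture per entity-second (",
           at, ")")
    if (sum(acts == id_sleep) > 1L)
      stop("combination error: duplicated Sleeping (", at, ")")
    if (id_eat %in% acts && !id_stand %in% acts)
      stop("combination error: Eating without Standing (", at, ")")
    if (anyDuplicated(acts))
      stop("combination error: duplicated action (", at, ")")
  }
  class(records) <- unique(c("ava_records", class(records)))
  records
}

#' Read AVA-style annotations from CSV
#'
#' Comma-separated rows `video_id,timestamp,x1,y1,x2,y2,action_id,entity_id`
#' (no header), normalized corner coordinates, 1-based action ids, integer
#' second timestamps. Input row order is preserved.
#'
#' @param path CSV path.
#' @param labels Label map used for validation.
#' @return Validated `ava_records`.
#' @export
read_ava_csv <- function(path, labels = default_label_map()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  cols <- c("video_id", "timestamp_s", "x1", "y1", "x2", "y2",
            "action_id", "entity_id")
  if (file.size(path) == 0L) {
    df <- as.data.frame(stats::setNames(
      list(character(), integer(), numeric(), numeric(), numeric(), numeric(),
           integer(), integer()), cols))
    return(validate_ava_records(df, labels))
  }
  df <- utils::read.csv(path, header = FALSE, col.names = cols,
                        colClasses = c("character", "integer", "numeric",
                                       "numeric", "numeric", "numeric",
                                       "integer", "integer"))
  validate_ava_records(df, labels)
}

#' Write AVA-style annotations to CSV
#'
#' Coordinates are serialized with 3 decimal places; the file is re-readable
#' by [read_ava_csv()]. UTF-8, LF line endings, no header.
#'
#' @param records Validated `ava_records`.
#' @param path Output path.
#' @param labels Label map used for validation before writing.
#' @return Number of rows written.
#' @export
write_ava_csv <- function(records, path, labels = default_label_map()) {
  records <- validate_ava_records(records, labels)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  if (nrow(records) > 0L) {
    lines <- sprintf("%s,%d,%.3f,%.3f,%.3f,%.3f,%d,%d",
                     records$video_id, records$timestamp_s,
                     records$x1, records$y1, records$x2, records$y2,
                     records$action_id, records$entity_id)
    writeLines(lines, con, sep = "\n")
  }
  nrow(records)
}

#' Read detector output from JSON
#'
#' A JSON array of objects with fields `video_id`, `timestamp_s`,
#' `box` (`[x1,y1,x2,y2]`, normalized) and `score` in `[0,1]` — the import
#' path for any external animal detector.
#'
#' @param path JSON path.
#' @return A `detection_records` data.frame with columns video_id,
#'   timestamp_s, x1, y1, x2, y2, score.
#' @export
read_detection_json <- function(path) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(raw) == 0L) {
    df <- data.frame(video_id = character(), timestamp_s = integer(),
                     x1 = numeric(), y1 = numeric(), x2 = numeric(),
                     y2 = numeric(), score = numeric())
    class(df) <- c("detection_records", "data.frame")
    return(df)
  }
  df <- do.call(rbind, lapply(raw, function(o) {
    data.frame(video_id = as.character(o$video_id),
               timestamp_s = as.integer(o$timestamp_s),
               x1 = o$box[[1]], y1 = o$box[[2]],
               x2 = o$box[[3]], y2 = o$box[[4]],
               score = as.numeric(o$score), stringsAsFactors = FALSE)
  }))
  validate_detections(df)
}

validate_detections <- function(df) {
  for (i in seq_len(nrow(df)))
    validate_box(unlist(df[i, c("x1", "y1", "x2", "y2")]),
                 where = paste0("detection ", i))
  if (any(df$score < 0 | df$score > 1))
    stop("detection score outside [0,1]")
  class(df) <- unique(c("detection_records", class(df)))
  df
}

#' Write detector output to JSON
#'
#' @param dets A `detection_records` data.frame (see [read_detection_json()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_json <- function(dets, path) {
  dets <- validate_detections(dets)
  objs <- lapply(seq_len(nrow(dets)), function(i) {
    list(video_id = dets$video_id[i],
         timestamp_s = dets$timestamp_s[i],
         box = c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i]),
         score = dets$score[i])
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}
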