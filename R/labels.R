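#' The built-in posture/behavior label taxonomy
#'
#' Five classes annotate stall-housed horses: three mutually exclusive body
#' postures (Standing; Sternal recumbency — lying on the chest, legs folded to
#' one side; Lateral recumbency — lying flat on the side) and two behaviors
#' that co-occur with a posture (Eating — head lowered to feed, only while
#' standing; Sleeping — may happen in any posture).
#'
#' @return A `label_map` object: data.frame with columns `id`, `name`, `kind`.
#' @export
default_label_map <- function() {
  lm <- data.frame(
    id = 1:5,
    name = c("Standing", "Sternal recumbency", "Lateral recumbency",
             "Eating", "Sleeping"),
    kind = c("posture", "posture", "posture", "behavior", "behavior"),
    stringsAsFactors = FALSE
  )
  class(lm) <- c("label_map", "data.frame")
  lm
}

validate_label_map <- function(lm) {
  if (!is.data.frame(lm) || !all(c("id", "name", "kind") %in% names(lm)))
    stop("label map must have columns id, name, kind")
  if (nrow(lm) == 0L) stop("label map is empty")
  if (anyDuplicated(lm$id)) stop("label map format error: duplicate ids")
  if (!identical(sort(as.integer(lm$id)), seq_len(nrow(lm))))
    stop("label map format error: ids must be contiguous starting at 1")
  if (!all(lm$kind %in% c("posture", "behavior")))
    stop("label map format error: unknown kind (must be posture or behavior)")
  if (anyDuplicated(lm$name)) stop("label map format error: duplicate names")
  lm <- lm[order(lm$id), , drop = FALSE]
  rownames(lm) <- NULL
  class(lm) <- c("label_map", "data.frame")
  lm
}

#' Load a label map from a tab-separated file
#'
#' One entry per line: `id<TAB>name<TAB>kind`, with `kind` either `posture`
#' or `behavior`. Ids must be unique and contiguous from 1.
#'
#' @param path Path to the TSV file, or `NULL` for the built-in default map.
#' @return A validated `label_map`.
#' @export
load_label_map <- function(path = NULL) {
  if (is.null(path)) return(default_label_map())
  if (!file.exists(path)) stop("label map file not found: ", path)
  lm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "name", "kind"),
                          colClasses = c("integer", "character", "character"),
                          quote = "", comment.char = "", encoding = "UTF-8")
  validate_label_map(lm)
}

#' Write a label map to a tab-separated file
#'
#' @param lm A `label_map`.
#' @param path Output path (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lm, path) {
  lm <- validate_label_map(lm)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d\t%s\t%s", lm$id, lm$name, lm$kind), con, sep = "\n")
  invisible(path)
}

label_id <- function(lm, name) {
  i <- match(name, lm$name)
  if (anyNA(i)) stop("unknown label name: ", paste(name[is.na(i)], collapse = ", "))
  lm$id[i]
}

posture_ids <- function(lm) lm$id[lm$kind == "posture"]
behavior_ids <- function(lm) lm$id[lm$kind == "behavior"]
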