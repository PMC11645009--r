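# Internal helpers: seed fan-out, numerics, image resize.

#' Derive a reproducible sub-seed from a global seed and a stream name
#'
#' Every stochastic operation in the package draws its seed through this
#' function so that a single global seed fans out into independent, named
#' substreams (corpus generation, splitting, augmentation, weight init, ...).
#'
#' @param seed Integer global seed.
#' @param key Character stream name.
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  val <- (abs(seed) %% 2147483647) * 69069 + h * 2654435761
  as.integer(val %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(sigmoid(x)) computed stably for |x| up to hundreds
log_sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- -log1p(exp(-x[pos]))
  out[!pos] <- x[!pos] - log1p(exp(x[!pos]))
  dim(out) <- dim(x)
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Bilinear image resize
#'
#' Resizes an image array by separable bilinear interpolation, implemented as
#' two small interpolation-matrix multiplications per channel.
#'
#' @param img Numeric matrix (H x W) or array (H x W x C).
#' @param h,w Target height and width in pixels.
#' @return Resized matrix or array with the same number of channels.
#' @export
resize_image <- function(img, h, w) {
  stopifnot(is.numeric(img), h >= 1, w >= 1)
  d <- dim(img)
  if (is.null(d) || length(d) < 2L) stop("img must be a matrix or array")
  H <- d[1]; W <- d[2]
  A <- interp_matrix(h, H)
  B <- t(interp_matrix(w, W))
  if (length(d) == 2L) return(A %*% img %*% B)
  out <- array(0, dim = c(h, w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% img[, , c] %*% B
  out
}

# n_out x n_in bilinear interpolation matrix (pixel-center aligned)
interp_matrix <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  lo <- pmin(pmax(floor(src), 1), n_in)
  hi <- pmin(lo + 1, n_in)
  frac <- pmin(pmax(src - lo, 0), 1)
  M <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  M[cbind(idx, lo)] <- M[cbind(idx, lo)] + (1 - frac)
  M[cbind(idx, hi)] <- M[cbind(idx, hi)] + frac
  M
}

# timestamped log line to stderr (and optional file connection)
sf_log <- function(..., level = "INFO", file = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}
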