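# Loss family for imbalanced multi-label classification: plain binary
# cross-entropy, class-weighted BCE, and their focal-modulated combinations.

#' Inverse-frequency class weights from positive-label counts
#'
#' For C classes with positive counts `n_i`, the weight of class i is
#' `w_i = (sum_j n_j) / (C * n_i)`: balanced counts give unit weights, and a
#' class with fewer instances contributes proportionally more to the loss.
#' Weights are invariant to rescaling all counts by a constant.
#'
#' @param counts Positive integer vector of per-class positive-label counts.
#' @return A `class_weights` object: list with `w` and `source_counts`.
#' @export
compute_class_weights <- function(counts) {
  if (length(counts) < 1L || any(!is.finite(counts)))
    stop("counts must be finite")
  if (any(counts <= 0))
    stop("zero (or negative) class count: merge or drop the class before ",
         "computing weights")
  C <- length(counts)
  w <- sum(counts) / (C * counts)
  structure(list(w = as.numeric(w), source_counts = counts),
            class = "class_weights")
}

as_weight_vector <- function(weights, C) {
  if (is.null(weights)) return(rep(1, C))
  w <- if (inherits(weights, "class_weights")) weights$w else as.numeric(weights)
  if (length(w) != C) stop("weight vector length ", length(w),
                           " does not match ", C, " classes")
  if (any(w <= 0)) stop("class weights must be positive")
  w
}

#' Class-weighted binary cross-entropy on logits
#'
#' Per-element loss for label `y` and logit `yhat`:
#' `-w_c * (y * log(sigmoid(yhat)) + (1 - y) * log(1 - sigmoid(yhat)))`,
#' computed with a numerically stable log-sigmoid so it stays finite for
#' extreme logits. With all weights 1 this is exactly plain BCE.
#'
#' @param y Binary label matrix (N x C) or vector.
#' @param yhat Logit matrix of the same shape.
#' @param weights `class_weights`, a length-C numeric vector, or NULL (all 1).
#' @return List with `loss` (mean over all N*C elements) and `elements`
#'   (per-element loss matrix).
#' @export
cw_loss <- function(y, yhat, weights = NULL) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!identical(dim(y), dim(yhat))) stop("y and yhat shapes differ")
  w <- as_weight_vector(weights, ncol(y))
  # y*log(p) + (1-y)*log(1-p) with p = sigmoid(yhat), stably:
  ll <- y * log_sigmoid(yhat) + (1 - y) * log_sigmoid(-yhat)
  el <- -sweep(ll, 2, w, "*")
  list(loss = mean(el), elements = el)
}

#' Plain binary cross-entropy on logits
#'
#' @inheritParams cw_loss
#' @return List with `loss` and `elements`, as [cw_loss()].
#' @export
bce_loss <- function(y, yhat) cw_loss(y, yhat, weights = NULL)

#' Focal modulation of a per-element loss
#'
#' Down-weights well-classified elements: each element loss `l` is replaced by
#' its product with the exponent `r` and the factor `(1 - p_t)^r`, where
#' `p_t` is the predicted probability of the true
#' binary outcome (`sigmoid(yhat)` if `y = 1`, else `1 - sigmoid(yhat)`). The
#' leading factor `r` is part of the formulation adopted here; set
#' `orthodox = TRUE` for the conventional `(1 - p_t)^r * l`. A warning is
#' issued for exponents outside `[2, 4]`, the range in which this modulation
#' behaves well in practice.
#'
#' @param elements Per-element loss matrix (N x C).
#' @param y Binary label matrix.
#' @param yhat Logit matrix.
#' @param r Focal exponent, integer >= 1 (default 2).
#' @param orthodox Drop the leading factor `r`.
#' @return List with `loss` (mean of modulated elements) and `elements`.
#' @export
focal_modulate <- function(elements, y, yhat, r = 2, orthodox = FALSE) {
  if (!is_scalar_number(r) || r < 1 || r != round(r))
    stop("focal exponent r must be an integer >= 1")
  if (r < 2 || r > 4)
    warning("focal exponent r = ", r, " outside [2, 4]; accuracy typically ",
            "degrades there", call. = FALSE)
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  p <- sigmoid(yhat)
  pt <- ifelse(y == 1, p, 1 - p)
  fac <- (1 - pt)^r
  if (!orthodox) fac <- r * fac
  el <- fac * elements
  list(loss = mean(el), elements = el)
}

#' Build a loss function from a configuration
#'
#' The four variants compared in this package: `bce` (plain binary
#' cross-entropy), `cw` (class-weighted BCE), and their focal-modulated
#' combinations `bce_f` and `cw_f`. The returned object evaluates the loss
#' and its analytic gradient with respect to the logits (the gradient is used
#' by the network trainer and is verified against finite differences in the
#' test suite).
#'
#' @param kind One of `"bce"`, `"cw"`, `"bce_f"`, `"cw_f"`.
#' @param weights `class_weights` (required for the `cw` variants).
#' @param r Focal exponent for the `_f` variants.
#' @param orthodox Passed to [focal_modulate()].
#' @return A `loss_fn` object: list with `$value(y, yhat)` -> scalar,
#'   `$grad(y, yhat)` -> matrix dLoss/dlogit, and the configuration fields.
#' @export
make_loss <- function(kind = c("cw_f", "bce", "cw", "bce_f"),
                      weights = NULL, r = 2, orthodox = FALSE) {
  kind <- match.arg(kind)
  focal <- kind %in% c("bce_f", "cw_f")
  weighted <- kind %in% c("cw", "cw_f")
  if (weighted && is.null(weights))
    stop("loss kind '", kind, "' requires class weights")
  if (!weighted) weights <- NULL
  if (focal && (!is_scalar_number(r) || r < 1 || r != round(r)))
    stop("focal exponent r must be an integer >= 1")

  value <- function(y, yhat) {
    base <- cw_loss(y, yhat, weights)
    if (!focal) return(base$loss)
    suppressWarnings(focal_modulate(base$elements, y, yhat, r, orthodox))$loss
  }

  grad <- function(y, yhat) {
    y <- as.matrix(y); yhat <- as.matrix(yhat)
    C <- ncol(y)
    w <- as_weight_vector(weights, C)
    wmat <- matrix(w, nrow(y), C, byrow = TRUE)
    p <- sigmoid(yhat)
    pt <- ifelse(y == 1, p, 1 - p)
    # d l / d yhat for l = -w*(y log p + (1-y) log(1-p)):  w*(p - y)
    dl <- wmat * (p - y)
    if (!focal) return(dl / length(y))
    lead <- if (orthodox) 1 else r
    el <- -wmat * (y * log_sigmoid(yhat) + (1 - y) * log_sigmoid(-yhat))
    # d pt / d yhat = p(1-p) for y=1, -p(1-p) for y=0
    dpt <- ifelse(y == 1, 1, -1) * p * (1 - p)
    dmod <- lead * ((1 - pt)^r * dl - r * (1 - pt)^(r - 1) * dpt * el)
    dmod / length(y)
  }

  structure(list(kind = kind, r = if (focal) r else NA_integer_,
                 weights = weights, orthodox = orthodox,
                 value = value, grad = grad),
            class = "loss_fn")
}
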