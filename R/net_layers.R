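# Low-level differentiable layers for the two-pathway video network.
#
# Feature maps are numeric arrays with named semantic dimensions
# (H, W, T, C). 3D convolution is computed as an im2col gather followed by a
# single BLAS matrix multiply; the gather index is built once per input
# shape and cached. Backward passes are hand-derived and checked against
# finite differences in the test suite.

.conv_cache <- new.env(parent = emptyenv())

# gather-index matrix (n_out_positions x kh*kw*kt*Cin) into the padded input
conv3d_index <- function(in_dim, kernel, stride, pad) {
  key <- paste(c(in_dim, kernel, stride, pad), collapse = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- in_dim[1]; W <- in_dim[2]; Tt <- in_dim[3]; Cin <- in_dim[4]
  kh <- kernel[1]; kw <- kernel[2]; kt <- kernel[3]
  sh <- stride[1]; sw <- stride[2]; st <- stride[3]
  ph <- pad[1]; pw <- pad[2]; pt <- pad[3]
  Hp <- H + 2 * ph; Wp <- W + 2 * pw; Tp <- Tt + 2 * pt
  Ho <- (Hp - kh) %/% sh + 1L
  Wo <- (Wp - kw) %/% sw + 1L
  To <- (Tp - kt) %/% st + 1L
  pos <- expand.grid(h = seq_len(Ho), w = seq_len(Wo), t = seq_len(To))
  pos_lin0 <- ((pos$h - 1) * sh) + ((pos$w - 1) * sw) * Hp +
    ((pos$t - 1) * st) * Hp * Wp
  off <- expand.grid(h = seq_len(kh), w = seq_len(kw), t = seq_len(kt),
                     c = seq_len(Cin))
  off_lin0 <- (off$h - 1) + (off$w - 1) * Hp + (off$t - 1) * Hp * Wp +
    (off$c - 1) * Hp * Wp * Tp
  idx <- outer(pos_lin0, off_lin0, "+") + 1L
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, out_dim = c(Ho, Wo, To),
              pad_dim = c(Hp, Wp, Tp, Cin))
  .conv_cache[[key]] <- out
  out
}

pad_map <- function(x, pad) {
  if (all(pad == 0)) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * pad[1], d[2] + 2 * pad[2],
                         d[3] + 2 * pad[3], d[4]))
  xp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
     pad[3] + seq_len(d[3]), ] <- x
  xp
}

unpad_map <- function(xp, pad, d) {
  if (all(pad == 0)) return(xp)
  xp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
     pad[3] + seq_len(d[3]), , drop = FALSE]
}

# x: (H,W,T,Cin); W_mat: (kh*kw*kt*Cin) x Cout; b: length Cout
conv3d_forward <- function(x, W_mat, b, kernel, stride, pad) {
  d <- dim(x)
  ci <- conv3d_index(d, kernel, stride, pad)
  xp <- pad_map(x, pad)
  P <- matrix(xp[ci$idx], nrow = nrow(ci$idx))
  out <- P %*% W_mat
  out <- sweep(out, 2, b, "+")
  dim(out) <- c(ci$out_dim, ncol(W_mat))
  list(out = out,
       cache = list(P = P, in_dim = d, kernel = kernel, stride = stride,
                    pad = pad, W_mat = W_mat))
}

conv3d_backward <- function(dout, cache) {
  ci <- conv3d_index(cache$in_dim, cache$kernel, cache$stride, cache$pad)
  n_pos <- nrow(ci$idx)
  dY <- matrix(dout, nrow = n_pos)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, cache$W_mat)
  dxp <- numeric(prod(ci$pad_dim))
  # scatter-add; per kernel-offset column the output->input map is injective,
  # so each column can be accumulated with one vectorized update
  for (k in seq_len(ncol(ci$idx))) {
    ix <- ci$idx[, k]
    dxp[ix] <- dxp[ix] + dP[, k]
  }
  dim(dxp) <- ci$pad_dim
  dx <- unpad_map(dxp, cache$pad, cache$in_dim)
  list(dx = dx, dW = dW, db = db)
}

# He-initialized convolution weights
init_conv <- function(kernel, cin, cout) {
  K <- prod(kernel) * cin
  list(W = matrix(stats::rnorm(K * cout, 0, sqrt(2 / K)), K, cout),
       b = numeric(cout))
}

# ---- squeeze-and-excitation ----------------------------------------------

#' Squeeze a feature map to a per-channel descriptor
#'
#' Global average pooling over the spatial and temporal dimensions: for a
#' feature map of shape H x W x T x C the result is the length-C vector of
#' channel means. Video feature maps carry a temporal axis, so the pool
#' includes T (see the methods vignette).
#'
#' @param u Numeric array H x W x T x C (or H x W x C).
#' @return Numeric vector of length C.
#' @export
se_squeeze <- function(u) {
  d <- dim(u)
  if (is.null(d) || !length(d) %in% c(3, 4)) stop("expected a 3- or 4-D map")
  C <- d[length(d)]
  colMeans(matrix(u, ncol = C))
}

#' Excitation: two-layer bottleneck with sigmoid gate
#'
#' `s = sigmoid(W2 %*% relu(W1 %*% z))`; each gate lies in (0, 1).
#'
#' @param z Squeezed channel descriptor, length C.
#' @param W1 Bottleneck weights, (C / ratio) x C.
#' @param W2 Expansion weights, C x (C / ratio).
#' @return Excitation weights `s`, length C.
#' @export
se_excite <- function(z, W1, W2) {
  if (ncol(W1) != length(z) || nrow(W2) != length(z) ||
      nrow(W1) != ncol(W2))
    stop("SE weight shapes inconsistent with channel count")
  as.vector(sigmoid(W2 %*% relu(W1 %*% z)))
}

#' Rescale feature-map channels by excitation weights
#'
#' @param u Feature map H x W x T x C.
#' @param s Excitation weights, length C.
#' @return Map of the same shape with channel c multiplied by `s[c]`.
#' @export
se_scale <- function(u, s) {
  d <- dim(u)
  if (length(s) != d[length(d)])
    stop("excitation length ", length(s), " does not match ", d[length(d)],
         " channels")
  u * rep(s, each = prod(d[-length(d)]))
}

se_forward <- function(x, W1, W2) {
  z <- se_squeeze(x)
  a <- as.vector(W1 %*% z)
  h <- relu(a)
  uvec <- as.vector(W2 %*% h)
  s <- sigmoid(uvec)
  list(out = se_scale(x, s),
       cache = list(x = x, z = z, a = a, h = h, s = s, W1 = W1, W2 = W2))
}

se_backward <- function(dout, cache) {
  d <- dim(cache$x)
  C <- d[4]
  hw <- prod(d[1:3])
  xm <- matrix(cache$x, ncol = C)
  dm <- matrix(dout, ncol = C)
  ds <- colSums(dm * xm)
  dx <- dout * rep(cache$s, each = hw)
  du <- ds * cache$s * (1 - cache$s)
  dW2 <- outer(du, cache$h)
  dh <- as.vector(crossprod(cache$W2, du))
  da <- dh * (cache$a > 0)
  dW1 <- outer(da, cache$z)
  dz <- as.vector(crossprod(cache$W1, da))
  dx <- dx + array(rep(dz, each = hw) / hw, dim = d)
  list(dx = dx, dW1 = dW1, dW2 = dW2)
}

# ---- region pooling -------------------------------------------------------

roi_cells <- function(box, Hf, Wf) {
  r1 <- min(Hf, max(1, floor(box[2] * Hf) + 1))
  r2 <- max(r1, min(Hf, ceiling(box[4] * Hf)))
  c1 <- min(Wf, max(1, floor(box[1] * Wf) + 1))
  c2 <- max(c1, min(Wf, ceiling(box[3] * Wf)))
  list(rows = r1:r2, cols = c1:c2)
}

# average pool the map over the box region and all of T -> length-C vector
roi_pool_forward <- function(x, box) {
  d <- dim(x)
  cells <- roi_cells(box, d[1], d[2])
  sub <- x[cells$rows, cells$cols, , , drop = FALSE]
  feat <- colMeans(matrix(sub, ncol = d[4]))
  list(out = feat, cache = list(dim = d, cells = cells))
}

roi_pool_backward <- function(dfeat, cache) {
  d <- cache$dim
  dx <- array(0, dim = d)
  n <- length(cache$cells$rows) * length(cache$cells$cols) * d[3]
  dx[cache$cells$rows, cache$cells$cols, , ] <-
    rep(dfeat / n, each = length(cache$cells$rows) * length(cache$cells$cols) * d[3])
  dx
}
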