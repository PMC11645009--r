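# The two-pathway recognizer: a slow pathway (few frames, wide channels) and
# a fast pathway (many frames, thin channels) with time-strided lateral
# connections feeding fast features into the slow branch, optional
# squeeze-and-excitation channel attention on the slow pathway, and a
# box-conditioned multi-label sigmoid head.

#' Network configuration
#'
#' Validates the dual-rate arithmetic: the slow pathway samples
#' `N_slow = window_len / s_slow` frames and the fast pathway
#' `N_fast = window_len / s_fast`; fast channels are `beta * c_slow`
#' (both must be positive integers). `se_placement` selects where channel
#' attention enters the slow pathway: `"end"` (after the last stage, before
#' region pooling — the default), `"front"` (after the stem), or `"none"`.
#'
#' @param backbone_depth `"tiny"` (2 blocks/stage, CPU-scale) or
#'   `"resnet50-3d"` (full-fidelity stage widths).
#' @param c_slow Base channel width of the slow pathway (tiny default 16,
#'   resnet50-3d default 64).
#' @param beta Fast/slow channel ratio (default 1/8).
#' @param window_len Clip window L in frames (default 64).
#' @param s_slow,s_fast Temporal strides (defaults 16, 2).
#' @param se_placement `"end"`, `"front"`, or `"none"`.
#' @param se_reduction SE bottleneck reduction ratio (default 16; clamped so
#'   the bottleneck keeps at least one unit).
#' @param num_classes Number of output labels (default 5).
#' @param lateral_connection_count Number of fast-to-slow fusion points
#'   (default: one per stage boundary of the chosen backbone).
#' @param input_size Square input resolution fed to the network (tiny
#'   default 32).
#' @return A `net_config` list.
#' @export
net_config <- function(backbone_depth = c("tiny", "resnet50-3d"),
                       c_slow = NULL, beta = 1 / 8, window_len = 64,
                       s_slow = 16, s_fast = 2,
                       se_placement = c("end", "front", "none"),
                       se_reduction = 16, num_classes = 5,
                       lateral_connection_count = NULL, input_size = NULL) {
  backbone_depth <- match.arg(backbone_depth)
  se_placement <- match.arg(se_placement)
  c_slow <- c_slow %||% if (backbone_depth == "tiny") 16 else 64
  input_size <- input_size %||% if (backbone_depth == "tiny") 32 else 224
  n_slow <- window_len / s_slow
  n_fast <- window_len / s_fast
  if (n_slow != round(n_slow) || n_fast != round(n_fast))
    stop("window_len must be divisible by both temporal strides")
  c_fast <- beta * c_slow
  if (c_fast != round(c_fast) || c_fast < 1)
    stop("beta * c_slow must be a positive integer (got ", c_fast, ")")
  n_stages <- if (backbone_depth == "tiny") 3L else 5L
  lateral_connection_count <- lateral_connection_count %||% (n_stages - 1L)
  if (lateral_connection_count > n_stages - 1L)
    stop("at most ", n_stages - 1L, " lateral connections for this backbone")
  structure(list(backbone_depth = backbone_depth,
                 c_slow = as.integer(c_slow), c_fast = as.integer(c_fast),
                 beta = beta, window_len = as.integer(window_len),
                 s_slow = as.integer(s_slow), s_fast = as.integer(s_fast),
                 n_slow = as.integer(n_slow), n_fast = as.integer(n_fast),
                 se_placement = se_placement,
                 se_reduction = as.integer(se_reduction),
                 num_classes = as.integer(num_classes),
                 lateral_connection_count = as.integer(lateral_connection_count),
                 input_size = as.integer(input_size)),
            class = "net_config")
}

# stage plan: per pathway a list of stages; each stage a list of blocks
# (kernel (kh,kw,kt), stride, cout, residual). Slow temporal kernels are 1
# except late stages; fast temporal kernels are 3 throughout.
stage_plan <- function(cfg) {
  cs <- cfg$c_slow; cf <- cfg$c_fast
  fast_c <- function(c) max(1L, as.integer(round(cfg$beta * c)))
  if (cfg$backbone_depth == "tiny") {
    widths <- as.integer(c(cs, round(1.5 * cs), 2L * cs))
    slow_kt <- c(1, 1, 1)
  } else {
    widths <- as.integer(c(cs, 4 * cs, 8 * cs, 16 * cs, 32 * cs))
    slow_kt <- c(1, 1, 1, 3, 3)
  }
  n_blocks <- if (cfg$backbone_depth == "tiny") c(1, 2, 2) else c(1, 3, 4, 6, 3)
  mk_path <- function(kt_vec, width_vec) {
    lapply(seq_along(width_vec), function(i) {
      lapply(seq_len(n_blocks[i]), function(j) {
        first <- j == 1L
        list(kernel = c(3, 3, kt_vec[i]),
             stride = if (first) c(2, 2, 1) else c(1, 1, 1),
             cout = width_vec[i], residual = !first)
      })
    })
  }
  list(slow = mk_path(slow_kt, widths),
       fast = mk_path(rep(3, length(widths)), vapply(widths, fast_c, integer(1))),
       widths = widths)
}

# lateral fusion stage indices: after stages 1..lateral_connection_count
lateral_points <- function(cfg) seq_len(cfg$lateral_connection_count)

#' Build a randomly initialized recognizer
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `sefast_model`: list with `params`, `cfg`, and the stage plan.
#' @export
build_sefast <- function(cfg = net_config(), seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "net_init"))
  plan <- stage_plan(cfg)
  params <- list()
  add_path <- function(params, path, name, cin0) {
    cin <- cin0
    for (i in seq_along(path)) {
      for (j in seq_along(path[[i]])) {
        bl <- path[[i]][[j]]
        p <- init_conv(bl$kernel, cin, bl$cout)
        params[[sprintf("%s_s%d_b%d_W", name, i, j)]] <- p$W
        params[[sprintf("%s_s%d_b%d_b", name, i, j)]] <- p$b
        cin <- bl$cout
      }
      # lateral features appended to the slow input of the next stage
      if (name == "slow" && i %in% lateral_points(cfg) && i < length(path)) {
        cf_i <- fast_width_at(plan, i)
        cin <- cin + 2L * cf_i
      }
    }
    params
  }
  params <- add_path(params, plan$slow, "slow", 3L)
  params <- add_path(params, plan$fast, "fast", 3L)
  for (i in lateral_points(cfg)) {
    cf_i <- fast_width_at(plan, i)
    p <- init_conv(c(1, 1, 5), cf_i, 2L * cf_i)
    params[[sprintf("lat%d_W", i)]] <- p$W
    params[[sprintf("lat%d_b", i)]] <- p$b
  }
  c_final <- slow_final_channels(cfg, plan)
  if (cfg$se_placement != "none") {
    c_se <- if (cfg$se_placement == "end") c_final else cfg$c_slow
    hd <- max(1L, c_se %/% cfg$se_reduction)
    # the squeezed descriptor is non-negative (post-ReLU maps), so W1 is
    # initialized half-normal to keep the narrow bottleneck alive at step 0
    params$se_W1 <- matrix(abs(stats::rnorm(hd * c_se, 0, sqrt(2 / c_se))),
                           hd, c_se)
    params$se_W2 <- matrix(stats::rnorm(c_se * hd, 0, sqrt(2 / hd)), c_se, hd)
  }
  cf_final <- fast_width_at(plan, length(plan$fast))
  d_in <- c_final + cf_final
  hidden <- max(16L, d_in)
  params$head_Wh <- matrix(stats::rnorm(d_in * hidden, 0, sqrt(2 / d_in)),
                           d_in, hidden)
  params$head_bh <- numeric(hidden)
  params$head_Wo <- matrix(stats::rnorm(hidden * cfg$num_classes, 0,
                                        sqrt(1 / hidden)),
                           hidden, cfg$num_classes)
  params$head_bo <- numeric(cfg$num_classes)
  structure(list(params = params, cfg = cfg, plan = plan),
            class = "sefast_model")
}

fast_width_at <- function(plan, i) {
  st <- plan$fast[[i]]
  st[[length(st)]]$cout
}

slow_final_channels <- function(cfg, plan) {
  st <- plan$slow[[length(plan$slow)]]
  st[[length(st)]]$cout
}

#' Fuse fast-pathway features into the slow pathway at one stage
#'
#' The fast feature map (temporal length 8x the slow map, from the 16/2
#' stride ratio) is passed through a time-strided convolution (temporal
#' kernel 5, stride 8, `2 * C_fast` output channels) and concatenated onto
#' the slow map's channels; spatial dimensions must match and are unchanged.
#'
#' @param fast_feat Fast feature map H x W x T_f x C_f.
#' @param slow_feat Slow feature map H x W x T_s x C_s with `T_f = 8 * T_s`.
#' @param W_mat,b Lateral convolution weights ((1*1*5*C_f) x 2C_f) and bias.
#' @return The fused slow map H x W x T_s x (C_s + 2 C_f).
#' @export
lateral_fuse <- function(fast_feat, slow_feat, W_mat, b) {
  df <- dim(fast_feat); ds <- dim(slow_feat)
  if (!all(df[1:2] == ds[1:2])) stop("incompatible spatial dims")
  if (df[3] != 8 * ds[3])
    stop("fast temporal length must be 8x the slow temporal length")
  fw <- conv3d_forward(fast_feat, W_mat, b, kernel = c(1, 1, 5),
                       stride = c(1, 1, 8), pad = c(0, 0, 2))
  fused <- array(0, dim = c(ds[1], ds[2], ds[3], ds[4] + dim(fw$out)[4]))
  fused[, , , seq_len(ds[4])] <- slow_feat
  fused[, , , ds[4] + seq_len(dim(fw$out)[4])] <- fw$out
  fused
}

# full forward pass for one clip; keep = TRUE retains caches for backprop
sefast_forward_full <- function(model, slow_in, fast_in, boxes, keep = FALSE) {
  cfg <- model$cfg; plan <- model$plan; P <- model$params
  caches <- list()
  run_path <- function(x, path, name) {
    for (i in seq_along(path)) {
      for (j in seq_along(path[[i]])) {
        bl <- path[[i]][[j]]
        nm <- sprintf("%s_s%d_b%d", name, i, j)
        cv <- conv3d_forward(x, P[[paste0(nm, "_W")]], P[[paste0(nm, "_b")]],
                             bl$kernel, bl$stride,
                             pad = floor(bl$kernel / 2))
        pre <- if (bl$residual) cv$out + x else cv$out
        out <- relu(pre)
        if (keep) caches[[nm]] <<- list(conv = cv$cache, pre = pre,
                                        residual = bl$residual)
        x <- out
      }
      if (keep) caches[[sprintf("%s_stage%d_out", name, i)]] <<- x
      assign(sprintf(".%s_stage%d", name, i), x, envir = stage_env)
    }
    x
  }
  stage_env <- new.env()
  xf <- run_path(fast_in, plan$fast, "fast")

  # slow pathway interleaved with lateral fusion and optional front SE
  x <- slow_in
  n_st <- length(plan$slow)
  for (i in seq_len(n_st)) {
    for (j in seq_along(plan$slow[[i]])) {
      bl <- plan$slow[[i]][[j]]
      nm <- sprintf("slow_s%d_b%d", i, j)
      cv <- conv3d_forward(x, P[[paste0(nm, "_W")]], P[[paste0(nm, "_b")]],
                           bl$kernel, bl$stride, pad = floor(bl$kernel / 2))
      pre <- if (bl$residual) cv$out + x else cv$out
      out <- relu(pre)
      if (keep) caches[[nm]] <- list(conv = cv$cache, pre = pre,
                                     residual = bl$residual)
      x <- out
    }
    if (i == 1L && cfg$se_placement == "front") {
      se <- se_forward(x, P$se_W1, P$se_W2)
      if (keep) caches$se <- se$cache
      x <- se$out
    }
    if (i %in% lateral_points(cfg) && i < n_st) {
      xf_i <- get(sprintf(".fast_stage%d", i), envir = stage_env)
      cs_before <- dim(x)[4]
      fw <- conv3d_forward(xf_i, P[[sprintf("lat%d_W", i)]],
                           P[[sprintf("lat%d_b", i)]],
                           kernel = c(1, 1, 5), stride = c(1, 1, 8),
                           pad = c(0, 0, 2))
      fused <- array(0, dim = c(dim(x)[1:3], cs_before + dim(fw$out)[4]))
      fused[, , , seq_len(cs_before)] <- x
      fused[, , , cs_before + seq_len(dim(fw$out)[4])] <- fw$out
      if (keep) caches[[sprintf("lat%d", i)]] <-
        list(conv = fw$cache, cs_before = cs_before)
      x <- fused
    }
  }
  if (cfg$se_placement == "end") {
    se <- se_forward(x, P$se_W1, P$se_W2)
    if (keep) caches$se <- se$cache
    x <- se$out
  }
  xs_final <- x
  xf_final <- xf

  n_box <- if (is.matrix(boxes)) nrow(boxes) else length(boxes)
  boxes_m <- if (is.matrix(boxes)) boxes else do.call(rbind, boxes)
  logits <- matrix(0, n_box, cfg$num_classes)
  box_caches <- vector("list", n_box)
  for (bi in seq_len(n_box)) {
    b <- as.numeric(boxes_m[bi, 1:4])
    rs <- roi_pool_forward(xs_final, b)
    rfst <- roi_pool_forward(xf_final, b)
    feat <- c(rs$out, rfst$out)
    a1 <- as.vector(crossprod(P$head_Wh, feat)) + P$head_bh
    h1 <- relu(a1)
    logits[bi, ] <- as.vector(crossprod(P$head_Wo, h1)) + P$head_bo
    if (keep) box_caches[[bi]] <- list(rs = rs$cache, rf = rfst$cache,
                                       feat = feat, a1 = a1, h1 = h1)
  }
  if (!keep) return(list(logits = logits))
  list(logits = logits,
       cache = list(caches = caches, box_caches = box_caches,
                    xs_final = xs_final, xf_final = xf_final,
                    slow_in = slow_in, fast_in = fast_in))
}

#' Forward pass: per-box multi-label logits
#'
#' Runs the two pathways on one clip pair, applies SE attention at the
#' configured placement, fuses the pathways, and classifies each region of
#' interest with an average-pooled box-conditioned head. Deterministic given
#' weights and inputs.
#'
#' @param model A `sefast_model`.
#' @param slow,fast Input tensors from [clip_tensor()].
#' @param boxes A matrix (n x 4) or list of normalized boxes; must be
#'   non-empty (detection is a prerequisite of recognition).
#' @return Logit matrix, one row per box, `num_classes` columns.
#' @export
sefast_forward <- function(model, slow, fast, boxes) {
  n_box <- if (is.matrix(boxes)) nrow(boxes) else length(boxes)
  if (n_box == 0L) stop("empty box list: recognition needs at least one box")
  sefast_forward_full(model, slow, fast, boxes, keep = FALSE)$logits
}

# backward for a single clip; dlogits: n_box x C
sefast_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg; plan <- model$plan; P <- model$params
  ca <- fwd$cache
  g <- list()
  acc <- function(name, val) {
    g[[name]] <<- if (is.null(g[[name]])) val else g[[name]] + val
  }
  dxs_final <- array(0, dim = dim(ca$xs_final))
  dxf_final <- array(0, dim = dim(ca$xf_final))
  for (bi in seq_len(nrow(dlogits))) {
    bc <- ca$box_caches[[bi]]
    dlog <- dlogits[bi, ]
    acc("head_Wo", outer(bc$h1, dlog))
    acc("head_bo", dlog)
    dh1 <- as.vector(P$head_Wo %*% dlog) * (bc$a1 > 0)
    acc("head_Wh", outer(bc$feat, dh1))
    acc("head_bh", dh1)
    dfeat <- as.vector(P$head_Wh %*% dh1)
    cs <- dim(ca$xs_final)[4]
    dxs_final <- dxs_final + roi_pool_backward(dfeat[seq_len(cs)], bc$rs)
    dxf_final <- dxf_final + roi_pool_backward(dfeat[-seq_len(cs)], bc$rf)
  }

  dx <- dxs_final
  if (cfg$se_placement == "end") {
    sb <- se_backward(dx, ca$caches$se)
    acc("se_W1", sb$dW1); acc("se_W2", sb$dW2)
    dx <- sb$dx
  }

  # walk the slow pathway backwards, peeling laterals
  n_st <- length(plan$slow)
  dfast_stage <- vector("list", length(plan$fast))  # grads into fast outputs
  for (i in rev(seq_len(n_st))) {
    if (i %in% lateral_points(cfg) && i < n_st) {
      lc <- ca$caches[[sprintf("lat%d", i)]]
      cs_before <- lc$cs_before
      d_all <- dim(dx)[4]
      dlat_out <- dx[, , , (cs_before + 1):d_all, drop = FALSE]
      dx <- dx[, , , seq_len(cs_before), drop = FALSE]
      cb <- conv3d_backward(dlat_out, lc$conv)
      acc(sprintf("lat%d_W", i), cb$dW)
      acc(sprintf("lat%d_b", i), cb$db)
      dfast_stage[[i]] <- if (is.null(dfast_stage[[i]])) cb$dx else
        dfast_stage[[i]] + cb$dx
    }
    if (i == 1L && cfg$se_placement == "front") {
      sb <- se_backward(dx, ca$caches$se)
      acc("se_W1", sb$dW1); acc("se_W2", sb$dW2)
      dx <- sb$dx
    }
    for (j in rev(seq_along(plan$slow[[i]]))) {
      nm <- sprintf("slow_s%d_b%d", i, j)
      blc <- ca$caches[[nm]]
      dpre <- dx * (blc$pre > 0)
      cb <- conv3d_backward(dpre, blc$conv)
      acc(paste0(nm, "_W"), cb$dW)
      acc(paste0(nm, "_b"), cb$db)
      dx <- if (blc$residual) cb$dx + dpre else cb$dx
    }
  }

  # fast pathway: final-stage grad from the head plus lateral taps
  dxf <- dxf_final
  for (i in rev(seq_along(plan$fast))) {
    if (!is.null(dfast_stage[[i]])) dxf <- dxf + dfast_stage[[i]]
    for (j in rev(seq_along(plan$fast[[i]]))) {
      nm <- sprintf("fast_s%d_b%d", i, j)
      blc <- ca$caches[[nm]]
      dpre <- dxf * (blc$pre > 0)
      cb <- conv3d_backward(dpre, blc$conv)
      acc(paste0(nm, "_W"), cb$dW)
      acc(paste0(nm, "_b"), cb$db)
      dxf <- if (blc$residual) cb$dx + dpre else cb$dx
    }
  }
  g
}

# ---- training -------------------------------------------------------------

#' Train the recognizer on clip samples
#'
#' Plain Adam on mini-batches of clips. Each sample is a list with `slow`,
#' `fast` ([clip_tensor()] output), `box` (normalized, the annotated animal),
#' and `y` (binary label vector). Deterministic given `seed`.
#'
#' @param samples List of training samples.
#' @param cfg A [net_config()].
#' @param loss A `loss_fn` from [make_loss()].
#' @param epochs Number of passes over the data.
#' @param lr Adam step size.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed (weights and shuffling).
#' @param verbose Log the per-epoch mean loss.
#' @return A trained `sefast_model` (with a `history` of epoch losses).
#' @export
train_sefast <- function(samples, cfg = net_config(), loss = NULL,
                         epochs = 8, lr = 4e-3, batch_size = 8, seed = 1,
                         verbose = FALSE) {
  stopifnot(length(samples) > 0)
  if (is.null(loss)) {
    counts <- pmax(1, colSums(do.call(rbind, lapply(samples, `[[`, "y"))))
    loss <- make_loss("cw_f", weights = compute_class_weights(counts), r = 2)
  }
  model <- build_sefast(cfg, seed)
  mstate <- list(); vstate <- list(); step <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "train_shuffle"))
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(samples))
    ep_loss <- 0; n_batches <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, length(ord))]
      grads <- list(); batch_loss <- 0
      for (si in idx) {
        s <- samples[[si]]
        fwd <- sefast_forward_full(model, s$slow, s$fast,
                                   matrix(s$box, 1), keep = TRUE)
        yrow <- matrix(s$y, 1)
        batch_loss <- batch_loss + loss$value(yrow, fwd$logits)
        dlogits <- loss$grad(yrow, fwd$logits)
        gi <- sefast_backward(model, fwd, dlogits)
        for (nm in names(gi))
          grads[[nm]] <- if (is.null(grads[[nm]])) gi[[nm]] else
            grads[[nm]] + gi[[nm]]
      }
      nb <- length(idx)
      step <- step + 1
      for (nm in names(grads)) {
        gr <- grads[[nm]] / nb
        if (is.null(mstate[[nm]])) {
          mstate[[nm]] <- gr * 0; vstate[[nm]] <- gr * 0
        }
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        model$params[[nm]] <- model$params[[nm]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + batch_loss / nb
      n_batches <- n_batches + 1
    }
    history[ep] <- ep_loss / n_batches
    if (verbose) sf_log(sprintf("epoch %d/%d loss %.5f", ep, epochs,
                                history[ep]))
  }
  model$history <- history
  model$loss_kind <- loss$kind
  model
}

#' Per-box class probabilities for a clip
#'
#' @param model Trained `sefast_model`.
#' @param slow,fast Clip tensors.
#' @param boxes Matrix or list of normalized boxes.
#' @return Matrix of sigmoid scores, one row per box.
#' @export
predict_sefast <- function(model, slow, fast, boxes) {
  sigmoid(sefast_forward(model, slow, fast, boxes))
}

#' Save / load a trained model
#'
#' The serialized file embeds the full configuration alongside the weights.
#'
#' @param model A `sefast_model`.
#' @param path File path (RDS).
#' @return `path` / the restored model.
#' @export
save_sefast <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sefast
#' @export
load_sefast <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sefast_model")) stop("not a saved recognizer: ", path)
  m
}
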