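test_that("network configuration enforces the dual-rate arithmetic", {
  cfg <- net_config()
  expect_equal(cfg$n_slow, 4L)           # 64 / 16
  expect_equal(cfg$n_fast, 32L)          # 64 / 2
  expect_equal(cfg$c_fast, 2L)           # 16 / 8 (tiny)
  full <- net_config("resnet50-3d")
  expect_equal(full$c_slow, 64L)
  expect_equal(full$c_fast, 8L)          # 64 / 8
  expect_error(net_config(window_len = 60), "divisible")
  expect_error(net_config(c_slow = 12), "positive integer")
  expect_error(net_config(lateral_connection_count = 5), "at most")
})

test_that("SE squeeze is the per-channel spatio-temporal mean", {
  u <- array(3.5, dim = c(4, 4, 2, 3))
  expect_equal(se_squeeze(u), c(3.5, 3.5, 3.5))
  u2 <- array(0, dim = c(2, 2, 2, 2))
  u2[, , , 1] <- 1; u2[, , , 2] <- -1
  expect_equal(se_squeeze(u2), c(1, -1))
  set.seed(12)
  u3 <- array(rnorm(16), dim = c(2, 2, 2, 2))
  # brute-force scalar summation per channel
  oracle <- c(sum(u3[, , , 1]) / 8, sum(u3[, , , 2]) / 8)
  expect_equal(se_squeeze(u3), oracle)
})

test_that("SE excitation follows sigma(W2 relu(W1 z))", {
  # zero descriptor gives 0.5 gates whatever the weights
  expect_equal(se_excite(c(0, 0), matrix(rnorm(2), 1), matrix(rnorm(2), 2)),
               c(0.5, 0.5))
  # scalar arithmetic: ratio 1, all-ones weights, z = (1,1)
  s <- se_excite(c(1, 1), matrix(c(1, 1), 1, 2), matrix(c(1, 1), 2, 1))
  expect_equal(s, rep(1 / (1 + exp(-2)), 2))
  # relu kills a negative hidden activation
  s2 <- se_excite(c(1, 1), matrix(c(-1, -1), 1, 2), matrix(c(3, 3), 2, 1))
  expect_equal(s2, c(0.5, 0.5))
  expect_error(se_excite(c(1, 1, 1), matrix(0, 1, 2), matrix(0, 2, 1)),
               "shapes")
})

test_that("SE scaling rescales channels and is the identity at unit gates", {
  set.seed(14)
  u <- array(rnorm(2 * 2 * 2 * 2), dim = c(2, 2, 2, 2))
  expect_identical(se_scale(u, c(1, 1)), u)
  expect_equal(se_scale(u, c(0, 0)), u * 0)
  out <- se_scale(u, c(0.5, 2))
  oracle <- u
  for (h in 1:2) for (w in 1:2) for (t in 1:2) {
    oracle[h, w, t, 1] <- u[h, w, t, 1] * 0.5
    oracle[h, w, t, 2] <- u[h, w, t, 2] * 2
  }
  expect_equal(out, oracle)
  expect_error(se_scale(u, c(1, 1, 1)), "channels")
})

test_that("lateral fusion concatenates time-strided fast features", {
  cf <- 2L
  fast <- array(rnorm(6 * 6 * 32 * cf), dim = c(6, 6, 32, cf))
  slow <- array(rnorm(6 * 6 * 4 * 8), dim = c(6, 6, 4, 8))
  W <- matrix(rnorm(5 * cf * 2 * cf, 0, 0.1), 5 * cf, 2 * cf)
  fused <- lateral_fuse(fast, slow, W, numeric(2 * cf))
  expect_equal(dim(fused), c(6, 6, 4, 8 + 2 * cf))   # C_slow + 2*C_fast
  # slow channels pass through untouched; zero fast features add zeros
  expect_equal(fused[, , , 1:8], slow)
  fused0 <- lateral_fuse(fast * 0, slow, W, numeric(2 * cf))
  expect_equal(fused0[, , , 9:12], array(0, c(6, 6, 4, 4)))
  expect_error(lateral_fuse(fast, array(0, c(5, 6, 4, 8)), W, numeric(4)),
               "spatial")
  expect_error(lateral_fuse(fast, array(0, c(6, 6, 5, 8)), W, numeric(4)),
               "8x")
})

test_that("forward pass honors the shape contract and per-box independence", {
  cfg <- net_config(input_size = 16)
  model <- build_sefast(cfg, seed = 2)
  set.seed(2)
  slow <- array(rnorm(16 * 16 * 4 * 3, 0, 0.3), c(16, 16, 4, 3))
  fast <- array(rnorm(16 * 16 * 32 * 3, 0, 0.3), c(16, 16, 32, 3))
  boxes <- rbind(c(0.1, 0.1, 0.6, 0.9), c(0.3, 0.2, 0.9, 0.8))
  logits <- sefast_forward(model, slow, fast, boxes)
  expect_equal(dim(logits), c(2, 5))
  # duplicating a box duplicates its logit row
  logits3 <- sefast_forward(model, slow, fast, boxes[c(1, 2, 1), ])
  expect_identical(logits3[1, ], logits3[3, ])
  expect_identical(logits3[1:2, ], logits)
  expect_error(sefast_forward(model, slow, fast, matrix(0, 0, 4)), "empty box")
  # deterministic given weights and inputs
  expect_identical(sefast_forward(model, slow, fast, boxes), logits)
})

test_that("SE is a no-op under forced unit excitation at every placement", {
  set.seed(3)
  slow <- array(rnorm(16 * 16 * 4 * 3, 0, 0.3), c(16, 16, 4, 3))
  fast <- array(rnorm(16 * 16 * 32 * 3, 0, 0.3), c(16, 16, 32, 3))
  box <- matrix(c(0.2, 0.2, 0.8, 0.8), 1)
  for (pl in c("front", "end")) {
    cfg_se <- net_config(input_size = 16, se_placement = pl)
    m <- build_sefast(cfg_se, seed = 4)
    base <- m
    base$cfg$se_placement <- "none"
    ref <- sefast_forward(base, slow, fast, box)
    with_se <- sefast_forward(m, slow, fast, box)
    expect_false(identical(ref, with_se))  # attention does something
    testthat::with_mocked_bindings(
      se_forward = function(x, W1, W2) list(out = x, cache = NULL),
      .package = "stallfast",
      code = {
        forced <- sefast_forward(m, slow, fast, box)
        expect_identical(forced, ref)      # unit gates == no SE, bitwise
      }
    )
  }
})

test_that("backpropagation matches finite differences on every group kind", {
  cfg <- net_config(input_size = 16, se_placement = "end")
  model <- build_sefast(cfg, seed = 3)
  set.seed(7)
  slow <- array(rnorm(16 * 16 * 4 * 3, 0, 0.3), c(16, 16, 4, 3))
  fast <- array(rnorm(16 * 16 * 32 * 3, 0, 0.3), c(16, 16, 32, 3))
  box <- matrix(c(0.2, 0.3, 0.7, 0.9), 1)
  y <- matrix(c(1, 0, 0, 1, 0), 1)
  loss <- make_loss("cw_f", weights = compute_class_weights(c(3, 9, 5, 2, 7)),
                    r = 2)
  fwd <- stallfast:::sefast_forward_full(model, slow, fast, box, keep = TRUE)
  g <- stallfast:::sefast_backward(model, fwd, loss$grad(y, fwd$logits))
  h <- 1e-5
  set.seed(8)
  for (nm in c("slow_s1_b1_W", "fast_s2_b2_W", "lat1_W", "lat2_b", "se_W1",
               "se_W2", "head_Wh", "head_bo")) {
    p <- model$params[[nm]]
    for (k in sample(length(p), min(3, length(p)))) {
      up <- model; up$params[[nm]][k] <- p[k] + h
      dn <- model; dn$params[[nm]][k] <- p[k] - h
      fd <- (loss$value(y, sefast_forward(up, slow, fast, box)) -
               loss$value(y, sefast_forward(dn, slow, fast, box))) / (2 * h)
      expect_equal(g[[nm]][k], fd, tolerance = 1e-4)
    }
  }
})

test_that("every trainable group receives gradient on a random batch", {
  cfg <- net_config(input_size = 16)
  model <- build_sefast(cfg, seed = 5)
  set.seed(9)
  slow <- array(rnorm(16 * 16 * 4 * 3, 0, 0.3), c(16, 16, 4, 3))
  fast <- array(rnorm(16 * 16 * 32 * 3, 0, 0.3), c(16, 16, 32, 3))
  box <- matrix(c(0.1, 0.1, 0.9, 0.9), 1)
  loss <- make_loss("bce")
  fwd <- stallfast:::sefast_forward_full(model, slow, fast, box, keep = TRUE)
  g <- stallfast:::sefast_backward(model, fwd,
                                   loss$grad(matrix(c(1, 0, 1, 0, 1), 1),
                                             fwd$logits))
  expect_setequal(names(g), names(model$params))
  for (nm in names(g)) expect_gt(max(abs(g[[nm]])), 0)
})

test_that("trained recognizer recovers the three postures on held-out data", {
  ds <- fix_dataset()
  y_test <- samples_labels(ds$test)
  macro_recalls <- vapply(1:3, function(sd) {
    m <- fix_model("cw_f", sd)
    met <- classifier_metrics(score_samples(m, ds$test), y_test)
    mean(met$recall[1:3])
  }, numeric(1))
  expect_gte(stats::median(macro_recalls), 0.8)
})

test_that("models round-trip through serialization with their config", {
  m <- build_sefast(net_config(input_size = 16), seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_sefast(m, path)
  m2 <- load_sefast(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg, m$cfg)
})
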