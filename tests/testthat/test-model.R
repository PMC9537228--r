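stream_weights <- function(model, which = c("jp", "rjdp")) {
  which <- match.arg(which)
  p <- model$params
  if (which == "jp") list(W = p$s1_W, b = p$s1_b)
  else list(W = p$s2_W, b = p$s2_b)
}

test_that("the default shape chain holds end to end", {
  p <- gait_sim_params()
  s <- preprocess_sample(simulate_walk(p, "healthy", 1))
  cfg <- fusion_net_config()
  m <- init_fusion_net(cfg, seed = 1)
  jp <- build_jp(s)
  rj <- build_rjdp(s)
  expect_equal(dim(jp$S), c(100, 20, 3))
  expect_equal(dim(rj$S_prime), c(100, 380, 3))
  f_jp <- forward_jp(jp, stream_weights(m, "jp"))
  f_rj <- forward_rjdp(rj, stream_weights(m, "rjdp"))
  expect_equal(dim(f_jp), c(98, 20, 3))
  expect_equal(dim(f_rj), c(98, 20, 3))
  f <- fuse(f_jp, f_rj)
  expect_equal(dim(f), c(98, 20, 6))
  pr <- classify(f, m)
  expect_length(pr, 4)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
})

test_that("stream convolutions match the brute-force direct oracle", {
  set.seed(11)
  for (rep in 1:3) {
    Tn <- sample(4:7, 1); J <- sample(3:5, 1); Cout <- sample(2:4, 1)
    s <- toy_sample(Tn = Tn, J = J, seed = rep)
    W1 <- array(rnorm(3 * 3 * Cout), c(3, 3, Cout)); b1 <- rnorm(Cout)
    expect_equal(forward_jp(build_jp(s), list(W = W1, b = b1)),
                 brute_conv_jp(s$positions, W1, b1), tolerance = 1e-5)
    W2 <- array(rnorm(3 * (J - 1) * 3 * Cout), c(3, (J - 1) * 3, Cout))
    b2 <- rnorm(Cout)
    rj <- build_rjdp(s)
    expect_equal(forward_rjdp(rj, list(W = W2, b = b2)),
                 brute_conv_rjdp(rj$S_prime, W2, b2, J), tolerance = 1e-5)
  }
})

test_that("stream-2 arithmetic: width J(J-1), kernel J-1, stride J-1 -> J", {
  # J = 3 toy: 6 pair columns collapse to 3 block placements
  s <- toy_sample(Tn = 4, J = 3, seed = 5)
  rj <- build_rjdp(s)
  W2 <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
  out <- forward_rjdp(rj, list(W = W2, b = c(0, 0)))
  expect_equal(dim(out), c(2, 3, 2))
  # a raw array with a non-J(J-1) width is a layout error
  expect_error(forward_rjdp(array(0, c(5, 7, 3)),
                            list(W = W2, b = c(0, 0))), "J")
})

test_that("degenerate filters behave linearly", {
  s <- toy_sample(Tn = 6, J = 4, seed = 2)
  zeroW <- list(W = array(0, c(3, 3, 3)), b = numeric(3))
  expect_true(all(forward_jp(build_jp(s), zeroW) == 0))
  rj <- build_rjdp(s)
  zeroW2 <- list(W = array(0, c(3, 9, 3)), b = numeric(3))
  expect_true(all(forward_rjdp(rj, zeroW2) == 0))
  # identity-like filter: center tap on the x channel reproduces x series
  W <- array(0, c(3, 3, 1)); W[2, 1, 1] <- 1
  out <- forward_jp(build_jp(s), list(W = W, b = 0))
  expect_equal(out[, , 1], s$positions[2:5, , 1], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("fuse concatenates channels in fixed order", {
  a <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  b <- array(0, c(2, 3, 3))
  f <- fuse(a, b)
  expect_equal(dim(f), c(2, 3, 6))
  expect_equal(f[, , 1:3], a)
  expect_true(all(f[, , 4:6] == 0))
  expect_false(identical(fuse(a, a + 1), fuse(a + 1, a)))
  expect_error(fuse(a, array(0, c(3, 3, 3))), "T2, J")
})

test_that("classify is softmax-normalized with expected degenerate cases", {
  cfg <- fusion_net_config(J = 4, T_target = 10,
                           post_fusion_channels = c(4L, 6L))
  m <- init_fusion_net(cfg, seed = 2)
  f <- array(rnorm(8 * 4 * 6), c(8, 4, 6))
  pr <- classify(f, m)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  # zero final layer: uniform distribution over E = 4 classes
  m0 <- m
  m0$params$fc_W[] <- 0
  m0$params$fc_b[] <- 0
  expect_equal(classify(f, m0), rep(0.25, 4), tolerance = 1e-12)
  # scaling all logits preserves the argmax
  m2 <- m
  m2$params$fc_W <- m$params$fc_W * 2
  m2$params$fc_b <- m$params$fc_b * 2
  expect_equal(which.max(classify(f, m2)), which.max(pr))
})

test_that("cross_entropy matches its closed forms", {
  expect_equal(cross_entropy(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0,
               tolerance = 1e-9)
  expect_equal(cross_entropy(rep(0.25, 4), c(0, 1, 0, 0)), log(4),
               tolerance = 1e-9)
  expect_equal(cross_entropy(c(0.5, 0.5), c(1, 0)), log(2),
               tolerance = 1e-9)
  # clamped rather than infinite at p_true = 0
  expect_true(is.finite(cross_entropy(c(0, 1), c(1, 0))))
  expect_error(cross_entropy(c(0.7, 0.6), c(1, 0)), "probability")
  expect_error(cross_entropy(c(0.5, 0.5), c(1, 1)), "one-hot")
})

test_that("ablation variants share the interface and differ as built", {
  cfg <- fusion_net_config(J = 5, T_target = 12,
                           post_fusion_channels = c(4L, 6L))
  f <- array(rnorm(10 * 5 * 6), c(10, 5, 6))
  ps <- list()
  for (v in c("full", "no_cnn", "sin_cnn", "no_maxp")) {
    m <- build_variant(v, cfg, seed = 3)
    pr <- classify(f, m)
    expect_length(pr, 4)
    expect_equal(sum(pr), 1, tolerance = 1e-6)
    ps[[v]] <- count_params(m)
  }
  expect_gt(ps$full, ps$sin_cnn)
  # no_cnn head has no convolution parameters after fusion
  m_nc <- build_variant("no_cnn", cfg, seed = 3)
  expect_false(any(c("h1_W", "h2_W") %in% names(m_nc$params)))
  expect_error(build_variant("resnet", cfg), "valid variants")
})

test_that("joint permutation equivariance of both streams", {
  s <- toy_sample(Tn = 6, J = 5, seed = 13)
  perm <- c(3, 1, 5, 2, 4)
  set.seed(14)
  W1 <- array(rnorm(27), c(3, 3, 3)); b1 <- rnorm(3)
  f1 <- forward_jp(build_jp(s), list(W = W1, b = b1))
  s_perm <- motion_sample(s$positions[, perm, , drop = FALSE], 100,
                          joint_names = s$joint_names[perm])
  f1p <- forward_jp(build_jp(s_perm), list(W = W1, b = b1))
  expect_equal(f1p, f1[, perm, , drop = FALSE], tolerance = 1e-12)

  # stream 2 on the blocked layout: permuting the J blocks permutes the
  # output placements identically (weights fixed)
  W2 <- array(rnorm(3 * 12 * 3), c(3, 12, 3)); b2 <- rnorm(3)
  blocked <- gaitfuse:::rjdp_blocked(build_rjdp(s))
  X <- aperm(array(blocked, c(dim(blocked), 1)), c(1, 2, 4, 3))
  y <- gaitfuse:::conv_t3_fwd(X, W2, b2, "valid")
  Xp <- X[, perm, , , drop = FALSE]
  yp <- gaitfuse:::conv_t3_fwd(Xp, W2, b2, "valid")
  expect_equal(yp, y[, perm, , , drop = FALSE], tolerance = 1e-12)
})

test_that("the fast positional stream-2 path equals the blocked path", {
  p <- gait_sim_params()
  s <- preprocess_sample(simulate_walk(p, "muscle_weakness", 9),
                         normalization_config(T_target = 20))
  cfg <- fusion_net_config(T_target = 20L, post_fusion_channels = c(4L, 6L))
  m <- init_fusion_net(cfg, seed = 6)
  feats <- lapply(list(s, s), gaitfuse:::sample_features, cfg = cfg,
                  blocked = TRUE)
  X <- gaitfuse:::assemble_batch(feats, cfg, blocked = TRUE)
  a2_blocked <- gaitfuse:::conv_t3_fwd(X$X2, m$params$s2_W, m$params$s2_b,
                                       "valid")
  a2_fast <- gaitfuse:::s2_fast_fwd(gaitfuse:::x1_flat(X$X1),
                                    m$params$s2_W, m$params$s2_b, 20, 3)
  expect_equal(a2_fast, a2_blocked, tolerance = 1e-10)
})

test_that("checkpoints round-trip and verify shapes on load", {
  cfg <- fusion_net_config(J = 5, T_target = 12,
                           post_fusion_channels = c(4L, 6L))
  m <- attach_attention(init_fusion_net(cfg, seed = 9))
  d <- withr::local_tempdir()
  f <- file.path(d, "model.rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_equal(m2$cfg$J, 5)
  s <- toy_sample(Tn = 12, J = 5, seed = 10, label = "healthy")
  expect_equal(predict_proba(m2, list(s)), predict_proba(m, list(s)))
  # corrupt a weight shape -> load refuses
  blob <- readRDS(f)
  blob$params$fc_W <- blob$params$fc_W[, 1:3]
  saveRDS(blob, f)
  expect_error(load_model(f), "fc_W")
})

test_that("analytic gradients match finite differences", {
  # eps is kept small so that central differences do not step across a
  # rectifier kink (which would corrupt the numerical oracle, not the
  # analytic gradient)
  eps <- 1e-7
  setups <- list(list(streams = "both", variant = "full"),
                 list(streams = "jp", variant = "no_maxp"),
                 list(streams = "rjdp", variant = "sin_cnn"))
  for (k in seq_along(setups)) {
    setup <- setups[[k]]
    set.seed(100 + k)
    cfg <- fusion_net_config(J = 4, T_target = 8, streams = setup$streams,
                             variant = setup$variant,
                             post_fusion_channels = c(3L, 4L))
    m <- init_fusion_net(cfg, seed = 4)
    # check at a generic point: zero-initialized biases would park some
    # pre-activations exactly on the rectifier kink, where the central
    # difference (but not the analytic subgradient) is ill-defined
    m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.05))
    B <- 3
    X <- list(X1 = array(rnorm(8 * 4 * B * 3), c(8, 4, B, 3)))
    y <- c(2, 4, 1)
    fw <- gaitfuse:::net_forward(m, X, keep_cache = TRUE)
    gr <- gaitfuse:::net_backward(m, X, fw, y)
    lossfn <- function(mm) gaitfuse:::batch_ce(
      gaitfuse:::net_forward(mm, X)$probs, y)
    pn <- gaitfuse:::trainable_params(m)
    worst <- 0
    for (nm in names(pn)) {
      for (ii in sample(seq_along(pn[[nm]]), min(4, length(pn[[nm]])))) {
        p2 <- pn
        p2[[nm]][ii] <- p2[[nm]][ii] + eps
        lp <- lossfn(gaitfuse:::write_back_params(m, p2))
        p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
        lm <- lossfn(gaitfuse:::write_back_params(m, p2))
        worst <- max(worst, abs((lp - lm) / (2 * eps) - gr[[nm]][ii]))
      }
    }
    expect_lt(worst, 1e-5)
  }
})
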