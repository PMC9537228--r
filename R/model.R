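#' Two-stream fusion network configuration
#'
#' Architecture of the classifier.  Stream 1 convolves the
#' joint-position tensor `S` with a `3 x 1 x C` filter (temporal kernel
#' `F_T = 3`, spatial kernel `F_J = 1`, both strides 1).  Stream 2
#' convolves the relative-displacement tensor `S'` with a
#' `3 x (J-1) x C` filter whose spatial stride equals its extent
#' `J - 1`, so each placement covers exactly one joint's correlation
#' block and the output spatial width matches stream 1's (`J`).  The
#' streams are concatenated in the channel dimension (mid-layer
#' fusion) and classified by a head whose layout depends on `variant`:
#'
#' * `full`    — two convolutions, adaptive max pooling, FC, softmax;
#' * `sin_cnn` — one convolution, pooling, FC;
#' * `no_cnn`  — pooling directly on the fused feature, FC;
#' * `no_maxp` — two convolutions, flatten, FC.
#'
#' @param J Joint count (default 20).
#' @param T_target Input frame count (default 100); stream
#'   convolutions are unpadded, so the fused feature has `T2 =
#'   T_target - 2` frames.
#' @param streams `"both"` for the fused two-stream network, `"jp"` or
#'   `"rjdp"` for the single-stream baselines.
#' @param variant Head architecture, see above.
#' @param stream_out_channels Output channels of each stream
#'   convolution (default `C = 3`, giving the `2C`-channel fused
#'   feature).
#' @param post_fusion_channels Widths of the two head convolutions
#'   (default `c(32, 64)`; temporal kernel 3, stride 1, same-padding,
#'   rectifier activation).
#' @param pool_output Spatial extent of the adaptive max pooling
#'   (fixed at 1, i.e. global max per channel).
#' @param E Number of classes (default 4).
#' @return A `fusion_net_config` object.
#' @export
fusion_net_config <- function(J = 20L, T_target = 100L,
                              streams = c("both", "jp", "rjdp"),
                              variant = c("full", "no_cnn", "sin_cnn",
                                          "no_maxp"),
                              stream_out_channels = 3L,
                              post_fusion_channels = c(32L, 64L),
                              pool_output = 1L, E = 4L) {
  streams <- match.arg(streams)
  variant <- match.arg(variant)
  if (E < 2) stopf("E must be >= 2")
  if (T_target < 3) stopf("T_target must be >= 3")
  if (length(post_fusion_channels) != 2)
    stopf("post_fusion_channels must give the two head conv widths")
  if (pool_output != 1L)
    stopf("only pool_output = 1 (global max per channel) is supported")
  structure(list(J = as.integer(J), T_target = as.integer(T_target),
                 C = 3L, streams = streams, variant = variant,
                 stream_out_channels = as.integer(stream_out_channels),
                 post_fusion_channels = as.integer(post_fusion_channels),
                 pool_output = 1L, E = as.integer(E),
                 F_T = 3L, F_J = 1L, F_D = as.integer(J) - 1L),
            class = "fusion_net_config")
}

# Channel count entering the head: 2C for the fused network, C per
# single stream.
head_in_channels <- function(cfg) {
  n_str <- if (cfg$streams == "both") 2L else 1L
  n_str * cfg$stream_out_channels
}

fc_in_features <- function(cfg) {
  T2 <- cfg$T_target - 2L
  w1 <- cfg$post_fusion_channels[1]; w2 <- cfg$post_fusion_channels[2]
  switch(cfg$variant,
         full = w2,
         sin_cnn = w1,
         no_cnn = head_in_channels(cfg),
         no_maxp = T2 * cfg$J * w2)
}

he_conv <- function(k, cin, cout) {
  array(stats::rnorm(3 * cin * cout, 0, sqrt(2 / (3 * cin))),
        c(3, cin, cout))
}

#' Initialize a fusion network
#'
#' He-normal weight initialization, deterministic given `seed`.
#'
#' @param cfg A [fusion_net_config()].
#' @param seed Integer seed.
#' @return A `fusion_net` model object (fields `cfg`, `params`,
#'   `attention`).
#' @export
init_fusion_net <- function(cfg, seed = 1L) {
  J1 <- cfg$J - 1L
  co <- cfg$stream_out_channels
  hin <- head_in_channels(cfg)
  w1 <- cfg$post_fusion_channels[1]; w2 <- cfg$post_fusion_channels[2]
  fin <- fc_in_features(cfg)
  params <- with_seed(seed, {
    p <- list()
    if (cfg$streams %in% c("both", "jp")) {
      p$s1_W <- he_conv(3, cfg$C, co); p$s1_b <- numeric(co)
    }
    if (cfg$streams %in% c("both", "rjdp")) {
      p$s2_W <- he_conv(3, J1 * cfg$C, co); p$s2_b <- numeric(co)
    }
    if (cfg$variant %in% c("full", "sin_cnn", "no_maxp")) {
      p$h1_W <- he_conv(3, hin, w1); p$h1_b <- numeric(w1)
    }
    if (cfg$variant %in% c("full", "no_maxp")) {
      p$h2_W <- he_conv(3, w1, w2); p$h2_b <- numeric(w2)
    }
    p$fc_W <- matrix(stats::rnorm(fin * cfg$E, 0, sqrt(2 / fin)),
                     fin, cfg$E)
    p$fc_b <- numeric(cfg$E)
    p
  })
  structure(list(cfg = cfg, params = params, attention = NULL),
            class = "fusion_net")
}

#' Build an ablation variant
#'
#' @param name One of `"full"`, `"no_cnn"`, `"sin_cnn"`, `"no_maxp"`.
#' @param cfg A [fusion_net_config()] supplying the remaining settings.
#' @param seed Integer seed for initialization.
#' @return An initialized `fusion_net`.
#' @export
build_variant <- function(name, cfg = fusion_net_config(), seed = 1L) {
  valid <- c("full", "no_cnn", "sin_cnn", "no_maxp")
  if (!name %in% valid)
    stopf("unknown variant '%s'; valid variants: %s", name,
          paste(valid, collapse = ", "))
  cfg$variant <- name
  init_fusion_net(cfg, seed = seed)
}

#' Trainable parameter count
#'
#' @param model A `fusion_net`.
#' @return Integer number of trainable scalars (including attention
#'   gates when attached).
#' @export
count_params <- function(model) {
  n <- sum(vapply(model$params, length, integer(1)))
  if (!is.null(model$attention))
    n <- n + length(model$attention$raw_jp) +
      length(model$attention$raw_rjdp)
  n
}

#' @export
print.fusion_net <- function(x, ...) {
  cat(sprintf("<fusion_net> streams=%s variant=%s J=%d T=%d params=%d%s\n",
              x$cfg$streams, x$cfg$variant, x$cfg$J, x$cfg$T_target,
              count_params(x),
              if (is.null(x$attention)) "" else " +attention"))
  invisible(x)
}

# ---- attention gating ------------------------------------------------

#' Attach channel-attention gates
#'
#' Inserts a learned sigmoid-bounded gating vector over the spatial
#' axis of each stream's input: length `J` over the joint columns of
#' `S` and length `D = J(J-1)` over the pair columns of `S'`.  Gates
#' are learned jointly with the network; their trained values are read
#' out as joint / joint-pair importance scores.  Fixing every gate
#' multiplier to 1 recovers the ungated model exactly.
#'
#' @param model A `fusion_net`.
#' @param init_gate Initial gate multiplier in (0, 1) (default 0.9).
#' @param gate_decay Coefficient of an L1 penalty on the gate
#'   multipliers (default 0.01).  The penalty lets gates on columns
#'   that do not help the classification decay toward 0 while columns
#'   the loss depends on sustain their gates, which is what makes the
#'   trained gate values readable as importance scores.  Set to 0 for
#'   unpenalized gates.
#' @return The model with an `attention` component.
#' @export
attach_attention <- function(model, init_gate = 0.9, gate_decay = 0.01) {
  cfg <- model$cfg
  raw0 <- log(init_gate / (1 - init_gate))
  att <- list(gate_decay = gate_decay)
  if (cfg$streams %in% c("both", "jp"))
    att$raw_jp <- rep(raw0, cfg$J)
  if (cfg$streams %in% c("both", "rjdp"))
    att$raw_rjdp <- rep(raw0, cfg$J * (cfg$J - 1L))
  att$fixed <- NULL
  model$attention <- att
  model
}

#' Fix attention gate multipliers (diagnostic)
#'
#' Overrides the learned gates with explicit multiplier vectors,
#' bypassing the sigmoid; `set_fixed_gates(model, jp = rep(1, J),
#' rjdp = rep(1, D))` reproduces the ungated model.
#'
#' @param model An attention-augmented `fusion_net`.
#' @param jp,rjdp Multiplier vectors (length `J` and `D`), or `NULL`
#'   to leave a stream's learned gate active.
#' @return The modified model.
#' @export
set_fixed_gates <- function(model, jp = NULL, rjdp = NULL) {
  if (is.null(model$attention)) stopf("model has no attention component")
  model$attention$fixed <- list(jp = jp, rjdp = rjdp)
  model
}

gate_values <- function(model) {
  att <- model$attention
  if (is.null(att)) return(NULL)
  g <- list()
  if (!is.null(att$raw_jp))
    g$jp <- if (!is.null(att$fixed$jp)) att$fixed$jp else sigmoid(att$raw_jp)
  if (!is.null(att$raw_rjdp))
    g$rjdp <- if (!is.null(att$fixed$rjdp)) att$fixed$rjdp
              else sigmoid(att$raw_rjdp)
  g
}

# Multiplier matrix over (joint, blocked-channel) realizing a length-D
# pair gate in the blocked stream-2 layout.
pair_gate_matrix <- function(g_rjdp, J, C = 3L) {
  J1 <- J - 1L
  M <- matrix(0, J, J1 * C)
  for (ch in seq_len(J1 * C)) {
    r <- (ch - 1L) %% J1 + 1L
    M[, ch] <- g_rjdp[(seq_len(J) - 1L) * J1 + r]
  }
  M
}

# Apply a (J, CH) multiplier matrix to a (T, J, B, CH) tensor.
apply_joint_channel_gate <- function(X, M) {
  Xp <- aperm(X, c(1, 2, 4, 3))               # (T, J, CH, B)
  d <- dim(Xp)
  fac <- rep(as.vector(M), each = d[1])        # (T, J, CH) pattern
  Xp <- Xp * fac                               # recycled over B
  aperm(Xp, c(1, 2, 4, 3))
}

# ---- checkpointing --------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the weights to a single serialized file and the
#' configuration to a JSON sidecar (`<path>.json`).
#'
#' @param model A `fusion_net`.
#' @param path Checkpoint file path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(list(params = model$params, attention = model$attention), path)
  cfg <- model$cfg
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Reads the weight store and its JSON config sidecar, and verifies
#' that every weight array has the shape the configuration implies.
#'
#' @param path Checkpoint file path written by [save_model()].
#' @return A `fusion_net`.
#' @export
load_model <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    stopf("checkpoint or its .json config sidecar missing at %s", path)
  blob <- readRDS(path)
  cj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- fusion_net_config(J = cj$J, T_target = cj$T_target,
                           streams = cj$streams, variant = cj$variant,
                           stream_out_channels = cj$stream_out_channels,
                           post_fusion_channels = cj$post_fusion_channels,
                           pool_output = cj$pool_output, E = cj$E)
  ref <- init_fusion_net(cfg, seed = 1L)
  if (!setequal(names(ref$params), names(blob$params)))
    stopf("checkpoint parameters do not match the configured architecture (%s)",
          paste(symdiff <- union(setdiff(names(ref$params), names(blob$params)),
                                 setdiff(names(blob$params), names(ref$params))),
                collapse = ", "))
  for (nm in names(ref$params)) {
    want <- dim(ref$params[[nm]]) %||% length(ref$params[[nm]])
    got <- dim(blob$params[[nm]]) %||% length(blob$params[[nm]])
    if (!identical(as.integer(want), as.integer(got)))
      stopf("checkpoint weight '%s' has shape %s; config implies %s", nm,
            paste(got, collapse = "x"), paste(want, collapse = "x"))
  }
  structure(list(cfg = cfg, params = blob$params,
                 attention = blob$attention),
            class = "fusion_net")
}

# ---- fast stream-2 path ---------------------------------------------
#
# Because every S' column is a difference of two joint positions, the
# stream-2 convolution (kernel 3 x (J-1) x C, stride J-1) is exactly a
# temporal kernel-3 convolution of the *position* tensor with an
# equivalent dense (J*C x J*O) spatial mixing matrix per tap:
#   out[t2, i, o] = sum_k sum_c [ (sum_r W[k, rc(r,c), o]) x[t2+k, i, c]
#                                 - sum_{j != i} W[k, rc(rank_ij, c), o]
#                                   x[t2+k, j, c] ]
# This avoids materializing the T x J(J-1) x C tensor in the training
# loop.  The blocked-tensor path is kept for attention-gated models
# (gates act on individual pair columns) and for the public API.

# Equivalent per-tap mixing matrices; rows (j + (c-1)J), cols (i + (o-1)J).
s2_equiv_matrices <- function(W2, J, C = 3L) {
  J1 <- J - 1L
  O <- dim(W2)[3]
  lapply(1:3, function(k) {
    Mk <- matrix(0, J * C, J * O)
    for (o in seq_len(O)) {
      for (cc in seq_len(C)) {
        wvec <- W2[k, (cc - 1L) * J1 + seq_len(J1), o]
        s <- sum(wvec)
        for (i in seq_len(J)) {
          col <- i + (o - 1L) * J
          rows_off <- setdiff(seq_len(J), i) + (cc - 1L) * J
          Mk[rows_off, col] <- Mk[rows_off, col] - wvec
          Mk[i + (cc - 1L) * J, col] <- Mk[i + (cc - 1L) * J, col] + s
        }
      }
    }
    Mk
  })
}

# X1: (T, J, B, C) positions -> flat (T, B, J*C) with j fastest.
x1_flat <- function(X1) {
  d <- dim(X1)
  Xf <- aperm(X1, c(1, 3, 2, 4))
  dim(Xf) <- c(d[1], d[3], d[2] * d[4])
  Xf
}

s2_fast_fwd <- function(Xf, W2, b2, J, C = 3L) {
  d <- dim(Xf); Tn <- d[1]; B <- d[2]
  T2 <- Tn - 2L
  O <- dim(W2)[3]
  M <- s2_equiv_matrices(W2, J, C)
  Yf <- matrix(0, T2 * B, J * O)
  for (k in 1:3) {
    Rk <- Xf[k:(k + T2 - 1L), , , drop = FALSE]
    dim(Rk) <- c(T2 * B, J * C)
    Yf <- Yf + Rk %*% M[[k]]
  }
  dim(Yf) <- c(T2, B, J, O)
  Y <- aperm(Yf, c(1, 3, 2, 4))                # (T2, J, B, O)
  for (o in seq_len(O)) Y[, , , o] <- Y[, , , o] + b2[o]
  Y
}

# Map the gradient of the equivalent mixing matrices back onto the
# blocked weight array W2 (3, (J-1)*C, O).
s2_fast_bwd <- function(Xf, dY, W2, J, C = 3L) {
  d <- dim(Xf); Tn <- d[1]; B <- d[2]
  T2 <- Tn - 2L
  O <- dim(W2)[3]; J1 <- J - 1L
  dYf <- aperm(dY, c(1, 3, 2, 4))              # (T2, B, J, O)
  dim(dYf) <- c(T2 * B, J * O)
  dW <- array(0, dim(W2))
  for (k in 1:3) {
    Rk <- Xf[k:(k + T2 - 1L), , , drop = FALSE]
    dim(Rk) <- c(T2 * B, J * C)
    dMk <- crossprod(Rk, dYf)                  # (J*C, J*O)
    for (o in seq_len(O)) {
      for (cc in seq_len(C)) {
        D <- dMk[(cc - 1L) * J + seq_len(J), (o - 1L) * J + seq_len(J)]
        Moff <- matrix(0, J1, J)
        for (i in seq_len(J)) Moff[, i] <- D[-i, i]
        dW[k, (cc - 1L) * J1 + seq_len(J1), o] <-
          sum(diag(D)) - rowSums(Moff)
      }
    }
  }
  db <- colSums(matrix(dY, prod(dim(dY)[1:3]), O))
  list(dW = dW, db = db)
}

# ---- batch forward / backward ---------------------------------------

# TRUE when the model must run stream 2 on the blocked pair tensor
# (attention gates act on individual pair columns); the ungated model
# uses the equivalent fast path on positions.
needs_blocked <- function(model) {
  model$cfg$streams %in% c("both", "rjdp") && !is.null(model$attention)
}

# Per-sample feature arrays for the network.  Positions are always
# kept (stream 1 input and the fast stream-2 path); the blocked pair
# tensor is built only when attention gates require it.
sample_features <- function(sample, cfg, blocked = FALSE) {
  out <- list(jp = build_jp(sample)$S)
  if (blocked && cfg$streams %in% c("both", "rjdp"))
    out$rjdp <- rjdp_blocked(build_rjdp(sample))
  out
}

# Stack per-sample features into batch arrays (T, J, B, C).
assemble_batch <- function(features, cfg, blocked = FALSE) {
  B <- length(features)
  Tn <- cfg$T_target; J <- cfg$J
  X1 <- array(0, c(Tn, J, B, cfg$C))
  for (b in seq_len(B)) X1[, , b, ] <- features[[b]]$jp
  out <- list(X1 = X1)
  if (blocked && cfg$streams %in% c("both", "rjdp")) {
    CH <- (J - 1L) * cfg$C
    X2 <- array(0, c(Tn, J, B, CH))
    for (b in seq_len(B)) X2[, , b, ] <- features[[b]]$rjdp
    out$X2 <- X2
  }
  out
}

# Full forward pass on batch arrays; returns probabilities and, when
# keep_cache, every intermediate needed by the backward pass.
net_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  has_jp <- cfg$streams %in% c("both", "jp")
  has_rj <- cfg$streams %in% c("both", "rjdp")
  blocked <- needs_blocked(model)
  g <- gate_values(model)
  cache <- list(g = g)
  parts <- list()
  if (has_jp) {
    X1g <- X$X1
    if (!is.null(g$jp)) {
      fac <- rep(g$jp, each = cfg$T_target)    # (T, J) pattern
      X1g <- X1g * as.vector(fac)              # recycled over B, C
    }
    a1 <- conv_t3_fwd(X1g, p$s1_W, p$s1_b, "valid")
    f1 <- relu_fwd(a1)
    parts$f1 <- f1
    if (keep_cache) { cache$X1g <- X1g; cache$a1 <- a1 }
  }
  if (has_rj && blocked) {
    X2g <- X$X2
    if (!is.null(g$rjdp)) {
      M <- pair_gate_matrix(g$rjdp, cfg$J, cfg$C)
      X2g <- apply_joint_channel_gate(X2g, M)
    }
    a2 <- conv_t3_fwd(X2g, p$s2_W, p$s2_b, "valid")
    f2 <- relu_fwd(a2)
    parts$f2 <- f2
    if (keep_cache) { cache$X2g <- X2g; cache$a2 <- a2 }
  } else if (has_rj) {
    Xf <- x1_flat(X$X1)
    a2 <- s2_fast_fwd(Xf, p$s2_W, p$s2_b, cfg$J, cfg$C)
    f2 <- relu_fwd(a2)
    parts$f2 <- f2
    if (keep_cache) { cache$Xf <- Xf; cache$a2 <- a2 }
  }
  f <- if (length(parts) == 2L) {
    d <- dim(parts$f1)
    co <- d[4]
    ff <- array(0, c(d[1], d[2], d[3], 2L * co))
    ff[, , , 1:co] <- parts$f1
    ff[, , , (co + 1L):(2L * co)] <- parts$f2
    ff
  } else parts[[1]]
  cache$f <- f
  z <- f
  if (cfg$variant %in% c("full", "sin_cnn", "no_maxp")) {
    b1 <- conv_t3_fwd(z, p$h1_W, p$h1_b, "same")
    z <- relu_fwd(b1)
    if (keep_cache) { cache$b1 <- b1; cache$z1 <- z }
  }
  if (cfg$variant %in% c("full", "no_maxp")) {
    b2 <- conv_t3_fwd(z, p$h2_W, p$h2_b, "same")
    z <- relu_fwd(b2)
    if (keep_cache) { cache$b2 <- b2; cache$z2 <- z }
  }
  if (cfg$variant == "no_maxp") {
    Zp <- aperm(z, c(1, 2, 4, 3))              # (T2, J, C, B)
    d <- dim(Zp)
    Zm <- Zp; dim(Zm) <- c(d[1] * d[2] * d[3], d[4])
    logits <- crossprod(Zm, p$fc_W)            # (B, E)
    logits <- sweep(logits, 2, p$fc_b, "+")
    if (keep_cache) cache$Zm <- Zm
  } else {
    pool <- pool_max_fwd(z)
    logits <- pool$P %*% p$fc_W
    logits <- sweep(logits, 2, p$fc_b, "+")
    if (keep_cache) cache$pool <- pool
  }
  probs <- softmax_rows(logits)
  if (!all(is.finite(probs)))
    stopf("non-finite activations in the forward pass")
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# Backward pass; y_idx are 1-based true class indices.
net_backward <- function(model, X, fw, y_idx) {
  cfg <- model$cfg; p <- model$params
  cache <- fw$cache
  B <- nrow(fw$probs)
  Y <- matrix(0, B, cfg$E)
  Y[cbind(seq_len(B), y_idx)] <- 1
  dlogits <- (fw$probs - Y) / B
  grads <- list()
  grads$fc_b <- colSums(dlogits)
  if (cfg$variant == "no_maxp") {
    grads$fc_W <- cache$Zm %*% dlogits
    dZm <- tcrossprod(p$fc_W, dlogits)         # (F, B)
    d2 <- dim(cache$z2)
    dZp <- array(dZm, c(d2[1], d2[2], d2[4], d2[3]))
    dz <- aperm(dZp, c(1, 2, 4, 3))
  } else {
    grads$fc_W <- crossprod(cache$pool$P, dlogits)
    dP <- tcrossprod(dlogits, p$fc_W)          # (B, C)
    dz <- pool_max_bwd(dP, cache$pool)
  }
  if (cfg$variant %in% c("full", "no_maxp")) {
    dz <- relu_bwd(cache$b2, dz)
    bw <- conv_t3_bwd(cache$z1, p$h2_W, dz, "same", need_dx = TRUE)
    grads$h2_W <- bw$dW; grads$h2_b <- bw$db
    dz <- bw$dX
  }
  if (cfg$variant %in% c("full", "sin_cnn", "no_maxp")) {
    dz <- relu_bwd(cache$b1, dz)
    bw <- conv_t3_bwd(cache$f, p$h1_W, dz, "same", need_dx = TRUE)
    grads$h1_W <- bw$dW; grads$h1_b <- bw$db
    dz <- bw$dX
  }
  # split fused gradient back into the streams
  has1 <- cfg$streams %in% c("both", "jp")
  has2 <- cfg$streams %in% c("both", "rjdp")
  blocked <- needs_blocked(model)
  co <- cfg$stream_out_channels
  df1 <- df2 <- NULL
  if (has1 && has2) {
    df1 <- dz[, , , 1:co, drop = FALSE]
    df2 <- dz[, , , (co + 1L):(2L * co), drop = FALSE]
  } else if (has1) df1 <- dz else df2 <- dz
  need_gate <- !is.null(model$attention) && is.null(model$attention$fixed)
  if (has1) {
    da1 <- relu_bwd(cache$a1, df1)
    bw <- conv_t3_bwd(cache$X1g, p$s1_W, da1, "valid",
                      need_dx = need_gate && !is.null(cache$g$jp))
    grads$s1_W <- bw$dW; grads$s1_b <- bw$db
    if (need_gate && !is.null(cache$g$jp)) {
      E1 <- bw$dX * X$X1
      d <- dim(E1)
      E1m <- E1; dim(E1m) <- c(d[1], d[2] * d[3] * d[4])
      s <- colSums(E1m)                        # over T
      dim(s) <- c(d[2], d[3] * d[4])
      dg <- rowSums(s)
      g1 <- cache$g$jp
      grads$att_raw_jp <- (dg + model$attention$gate_decay) * g1 * (1 - g1)
    }
  }
  if (has2 && !blocked) {
    da2 <- relu_bwd(cache$a2, df2)
    bw <- s2_fast_bwd(cache$Xf, da2, p$s2_W, cfg$J, cfg$C)
    grads$s2_W <- bw$dW; grads$s2_b <- bw$db
  } else if (has2) {
    da2 <- relu_bwd(cache$a2, df2)
    bw <- conv_t3_bwd(cache$X2g, p$s2_W, da2, "valid",
                      need_dx = need_gate && !is.null(cache$g$rjdp))
    grads$s2_W <- bw$dW; grads$s2_b <- bw$db
    if (need_gate && !is.null(cache$g$rjdp)) {
      E2 <- bw$dX * X$X2
      d <- dim(E2)                             # (T, J, B, CH)
      s_jch <- apply(E2, c(2, 4), sum)         # (J, CH)
      J1 <- cfg$J - 1L
      S3 <- array(s_jch, c(cfg$J, J1, cfg$C))
      dgmat <- S3[, , 1] + S3[, , 2] + S3[, , 3]   # (J, J1)
      dg <- as.vector(t(dgmat))
      g2 <- cache$g$rjdp
      grads$att_raw_rjdp <- (dg + model$attention$gate_decay) * g2 * (1 - g2)
    }
  }
  grads
}

#' Predicted class probabilities
#'
#' @param model A `fusion_net`.
#' @param samples List of normalized [motion_sample()]s.
#' @return `length(samples) x E` matrix of softmax probabilities, with
#'   [gait_classes()] as column names when `E = 4`.
#' @export
predict_proba <- function(model, samples) {
  cfg <- model$cfg
  blocked <- needs_blocked(model)
  feats <- lapply(samples, sample_features, cfg = cfg, blocked = blocked)
  X <- assemble_batch(feats, cfg, blocked = blocked)
  probs <- net_forward(model, X)$probs
  if (cfg$E == 4L) colnames(probs) <- gait_classes()
  probs
}

# ---- op-level single-sample wrappers --------------------------------

as_stream_batch <- function(S) {
  d <- dim(S)
  aperm(array(S, c(d, 1L)), c(1, 2, 4, 3))     # (T, J, 1, C)
}

#' Stream-1 convolution on one sample
#'
#' Applies the `F_T = 3`, `F_J = 1` joint-position convolution (stride
#' 1, no temporal padding) to a `T x J x 3` tensor.
#'
#' @param S A `joint_position_tensor` from [build_jp()] or a
#'   `T x J x 3` array.
#' @param weights List with `W` (`3 x 3 x Cout` array) and `b`
#'   (length-`Cout` bias).
#' @return `(T-2) x J x Cout` feature array `f_jp`.
#' @export
forward_jp <- function(S, weights) {
  if (inherits(S, "joint_position_tensor")) S <- S$S
  if (length(dim(S)) != 3L || dim(S)[3] != 3L)
    stopf("S must be a T x J x 3 array")
  if (dim(S)[1] < 3L) stopf("T = %d too small for temporal kernel 3",
                            dim(S)[1])
  Y <- conv_t3_fwd(as_stream_batch(S), weights$W, weights$b, "valid")
  d <- dim(Y)
  array(aperm(Y, c(1, 2, 4, 3)), c(d[1], d[2], d[4]))
}

#' Stream-2 convolution on one sample
#'
#' Applies the `F_T = 3`, `F_D = J - 1` relative-displacement
#' convolution with spatial stride `J - 1`, so placement `k` covers
#' joint `k`'s correlation block and the output spatial width is `J`.
#'
#' @param S_prime A `relative_displacement_tensor` from [build_rjdp()]
#'   or a `T x J(J-1) x 3` array.
#' @param weights List with `W` (`3 x (J-1)*3 x Cout` array, blocked
#'   channel layout: pair offset fastest, coordinate slowest) and `b`.
#' @return `(T-2) x J x Cout` feature array `f_rjdp`.
#' @export
forward_rjdp <- function(S_prime, weights) {
  if (inherits(S_prime, "relative_displacement_tensor")) {
    blocked <- rjdp_blocked(S_prime)
  } else {
    D <- dim(S_prime)[2]
    J <- (1 + sqrt(1 + 4 * D)) / 2
    if (abs(J - round(J)) > 1e-9)
      stopf("spatial width %d is not J(J-1) for any integer J: cannot form stride J-1 blocks", D)
    J <- as.integer(round(J))
    blocked <- rjdp_blocked(list(S_prime = S_prime, J = J))
  }
  d <- dim(blocked)
  X <- aperm(array(blocked, c(d, 1L)), c(1, 2, 4, 3))
  Y <- conv_t3_fwd(X, weights$W, weights$b, "valid")
  dy <- dim(Y)
  array(aperm(Y, c(1, 2, 4, 3)), c(dy[1], dy[2], dy[4]))
}

#' Mid-layer fusion of the two stream features
#'
#' Channel concatenation, `f_jp` first.
#'
#' @param f_jp,f_rjdp `T2 x J x C` feature arrays sharing `(T2, J)`.
#' @return `T2 x J x 2C` fused feature array.
#' @export
fuse <- function(f_jp, f_rjdp) {
  d1 <- dim(f_jp); d2 <- dim(f_rjdp)
  if (!identical(d1[1:2], d2[1:2]))
    stopf("stream outputs disagree on (T2, J): %s vs %s — the size-matching contract was violated upstream",
          paste(d1[1:2], collapse = "x"), paste(d2[1:2], collapse = "x"))
  out <- array(0, c(d1[1], d1[2], d1[3] + d2[3]))
  out[, , seq_len(d1[3])] <- f_jp
  out[, , d1[3] + seq_len(d2[3])] <- f_rjdp
  out
}

#' Classification head on one fused feature
#'
#' Runs the model's post-fusion head (convolutions / pooling / FC per
#' its variant) on a single fused feature tensor.
#'
#' @param f `T2 x J x C_head` fused feature array.
#' @param model A `fusion_net` whose head accepts `C_head` channels.
#' @return Length-`E` softmax probability vector.
#' @export
classify <- function(f, model) {
  cfg <- model$cfg; p <- model$params
  z <- as_stream_batch(f)
  if (cfg$variant %in% c("full", "sin_cnn", "no_maxp"))
    z <- relu_fwd(conv_t3_fwd(z, p$h1_W, p$h1_b, "same"))
  if (cfg$variant %in% c("full", "no_maxp"))
    z <- relu_fwd(conv_t3_fwd(z, p$h2_W, p$h2_b, "same"))
  if (cfg$variant == "no_maxp") {
    Zp <- aperm(z, c(1, 2, 4, 3))
    v <- as.vector(Zp)
    logits <- as.vector(v %*% p$fc_W) + p$fc_b
  } else {
    P <- pool_max_fwd(z)$P
    logits <- as.vector(P %*% p$fc_W) + p$fc_b
  }
  pr <- exp(logits - max(logits))
  pr <- pr / sum(pr)
  if (!all(is.finite(pr))) stopf("non-finite activations in classify")
  pr
}
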