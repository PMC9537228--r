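# Independent brute-force oracles and tiny fixture builders.

# random motion sample on an arbitrary toy skeleton
toy_sample <- function(Tn = 4, J = 3, seed = 1, label = "healthy") {
  set.seed(seed)
  motion_sample(array(rnorm(Tn * J * 3), c(Tn, J, 3)),
                frame_rate = 100, label = label,
                sample_id = sprintf("toy%d", seed),
                joint_names = paste0("j", seq_len(J)))
}

# brute-force relative displacements: double loop over ordered pairs
brute_rjdp <- function(pos) {
  Tn <- dim(pos)[1]; J <- dim(pos)[2]
  out <- array(NA_real_, c(Tn, J * (J - 1), 3))
  col <- 0L
  for (i in seq_len(J)) {
    for (j in seq_len(J)) {
      if (i == j) next
      col <- col + 1L
      out[, col, ] <- pos[, i, ] - pos[, j, ]
    }
  }
  out
}

# brute-force stream-1 convolution: kernel (3, 1, C), stride 1, valid
brute_conv_jp <- function(S, W, b) {
  Tn <- dim(S)[1]; J <- dim(S)[2]; Cout <- dim(W)[3]
  out <- array(0, c(Tn - 2, J, Cout))
  for (t in seq_len(Tn - 2)) for (j in seq_len(J)) for (o in seq_len(Cout)) {
    acc <- b[o]
    for (k in 1:3) for (cc in 1:3)
      acc <- acc + W[k, cc, o] * S[t + k - 1, j, cc]
    out[t, j, o] <- acc
  }
  out
}

# brute-force stream-2 convolution: kernel (3, J-1, C), stride (1, J-1),
# applied to the T x J(J-1) x 3 pair tensor; W is (3, (J-1)*3, Cout)
# with within-block pair offset fastest in the channel index.
brute_conv_rjdp <- function(Sp, W, b, J) {
  Tn <- dim(Sp)[1]; J1 <- J - 1; Cout <- dim(W)[3]
  out <- array(0, c(Tn - 2, J, Cout))
  for (t in seq_len(Tn - 2)) for (i in seq_len(J)) for (o in seq_len(Cout)) {
    acc <- b[o]
    for (k in 1:3) for (r in seq_len(J1)) for (cc in 1:3)
      acc <- acc + W[k, r + (cc - 1) * J1, o] *
        Sp[t + k - 1, (i - 1) * J1 + r, cc]
    out[t, i, o] <- acc
  }
  out
}

# brute-force per-class metrics from labels and predictions
brute_prf <- function(y_true, y_pred, cl) {
  tp <- sum(y_true == cl & y_pred == cl)
  fp <- sum(y_true != cl & y_pred == cl)
  fn <- sum(y_true == cl & y_pred != cl)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

# brute-force AUC: probability a random positive outscores a random
# negative (ties count half)
brute_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# small strongly-separable cohort for training tests
strong_cohort <- function(counts, seed = 101, T_target = 50) {
  params <- gait_sim_params()
  co <- generate_cohort(params, counts, seed = seed)
  lapply(co, preprocess_sample,
         config = normalization_config(T_target = T_target))
}
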