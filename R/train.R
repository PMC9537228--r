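#' Training configuration
#'
#' Defaults follow the published protocol: 80 epochs of Adam at
#' learning rate 0.003 with batch size 57, evaluated by 5-fold
#' cross-validation.  The batch size is honored even when a training
#' fold is smaller (one batch per epoch then).
#'
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param k_folds Cross-validation fold count.
#' @param seed Integer seed controlling initialization, shuffling and
#'   fold assignment.
#' @param device Compute target name (only `"cpu"` is available).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 80L, learning_rate = 0.003,
                         batch_size = 57L, k_folds = 5L, seed = 1L,
                         device = "cpu") {
  if (epochs < 1 || batch_size < 1 || k_folds < 1)
    stopf("epochs, batch_size and k_folds must be positive")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 device = device, optimizer = "adam"),
            class = "train_config")
}

#' Stratified k-fold split
#'
#' Partitions sample indices into `k` test folds preserving class
#' proportions as closely as integer arithmetic allows, with overall
#' fold sizes as equal as possible.  Classes smaller than `k` are
#' spread round-robin over the emptiest folds (with a warning, since
#' at least one test fold must then lack that class).  Deterministic
#' given `seed`.
#'
#' @param labels Character vector of class labels.
#' @param k Fold count (`2 <= k <= length(labels)`).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train =, test =)` index
#'   vectors; the test sets partition `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2 || k > n)
    stopf("k must satisfy 2 <= k <= n (= %d), got %d", n, k)
  tab <- sort(table(labels), decreasing = TRUE)
  fold_of <- integer(n)
  totals <- integer(k)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      m <- length(idx)
      if (m < k)
        warnf("class '%s' has %d member(s) for %d folds; at least one test fold will lack it",
              cl, m, k)
      idx <- idx[sample.int(m)]
      base <- m %/% k
      rem <- m - base * k
      alloc <- rep(base, k)
      if (rem > 0) {
        ord <- order(totals, seq_len(k))
        alloc[ord[seq_len(rem)]] <- base + 1L
      }
      pos <- 1L
      for (f in seq_len(k)) {
        if (alloc[f] > 0L) {
          fold_of[idx[pos:(pos + alloc[f] - 1L)]] <- f
          pos <- pos + alloc[f]
        }
      }
      totals <- totals + alloc
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

# Combined trainable parameter list (network weights + attention raws).
trainable_params <- function(model) {
  p <- model$params
  if (!is.null(model$attention) && is.null(model$attention$fixed)) {
    if (!is.null(model$attention$raw_jp))
      p$att_raw_jp <- model$attention$raw_jp
    if (!is.null(model$attention$raw_rjdp))
      p$att_raw_rjdp <- model$attention$raw_rjdp
  }
  p
}

write_back_params <- function(model, p) {
  model$params[names(model$params)] <- p[names(model$params)]
  if (!is.null(p$att_raw_jp)) model$attention$raw_jp <- as.vector(p$att_raw_jp)
  if (!is.null(p$att_raw_rjdp))
    model$attention$raw_rjdp <- as.vector(p$att_raw_rjdp)
  model
}

#' Train a model on one fold
#'
#' End-to-end training with Adam on mini-batches; logs the mean
#' training loss per epoch.  Deterministic given the seeds in the
#' configurations.
#'
#' @param train_samples List of normalized [motion_sample()]s (real
#'   plus mixup-synthetic).
#' @param cfg_model A [fusion_net_config()].
#' @param cfg_train A [train_config()].
#' @param model Optional pre-built `fusion_net` (e.g. attention-
#'   augmented); initialized from `cfg_model` when `NULL`.
#' @return List with `model` (fitted) and `loss_log` (numeric vector,
#'   one mean training loss per epoch).
#' @export
train_fold <- function(train_samples, cfg_model, cfg_train,
                       model = NULL) {
  if (length(train_samples) == 0) stopf("empty training set")
  if (is.null(model))
    model <- init_fusion_net(cfg_model, seed = derive_seed(cfg_train$seed, 1L))
  cfg <- model$cfg
  labels <- cohort_labels(train_samples)
  y_idx <- match(labels, gait_classes())
  if (anyNA(y_idx)) stopf("unlabelled sample in training set")
  blocked <- needs_blocked(model)
  feats <- lapply(train_samples, sample_features, cfg = cfg,
                  blocked = blocked)
  Xall <- assemble_batch(feats, cfg, blocked = blocked)
  n <- length(train_samples)
  params <- trainable_params(model)
  state <- adam_init(params)
  loss_log <- numeric(cfg_train$epochs)
  with_seed(derive_seed(cfg_train$seed, 2L), {
    for (ep in seq_len(cfg_train$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg_train$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        take <- ord[starts[bi]:min(starts[bi] + cfg_train$batch_size - 1L, n)]
        Xb <- list()
        if (!is.null(Xall$X1)) Xb$X1 <- gather_batch(Xall$X1, take)
        if (!is.null(Xall$X2)) Xb$X2 <- gather_batch(Xall$X2, take)
        fw <- net_forward(model, Xb, keep_cache = TRUE)
        loss <- batch_ce(fw$probs, y_idx[take])
        if (!is.finite(loss))
          stopf("divergent training loss at epoch %d, batch %d", ep, bi)
        losses[bi] <- loss
        grads <- net_backward(model, Xb, fw, y_idx[take])
        upd <- adam_step(params, grads, state, cfg_train$learning_rate)
        params <- upd$params
        state <- upd$state
        model <- write_back_params(model, params)
      }
      loss_log[ep] <- mean(losses)
    }
  })
  list(model = model, loss_log = loss_log)
}

#' Evaluate a fitted model on a test set
#'
#' Argmax predictions from softmax probabilities, summarized by
#' [metrics_report()]; also records the mean test cross-entropy.
#'
#' @param model A fitted `fusion_net`.
#' @param test_samples Non-empty list of labelled, normalized
#'   [motion_sample()]s.
#' @return A `metrics_report` with an extra `test_loss` field.
#' @export
evaluate <- function(model, test_samples) {
  if (length(test_samples) == 0) stopf("empty test set")
  labels <- cohort_labels(test_samples)
  probs <- predict_proba(model, test_samples)
  rep <- metrics_report(labels, probs)
  rep$test_loss <- batch_ce(probs, match(labels, gait_classes()))
  rep
}

#' Cross-validated training and evaluation
#'
#' For each of `k` stratified folds: balance the training folds with
#' mixup (synthetic samples never enter a test fold), train for the
#' configured epochs, and evaluate on the held-out fold.  The
#' aggregate report sums the per-fold confusion matrices (every real
#' sample is tested exactly once) and averages the per-fold metrics.
#'
#' @param samples List of labelled, normalized [motion_sample()]s.
#' @param cfg_model A [fusion_net_config()].
#' @param cfg_train A [train_config()].
#' @param spec A [mixup_spec()]; augmentation is rerun inside each
#'   split on the training folds only.  `NULL` disables augmentation.
#' @param keep_models Keep the fitted per-fold models (needed for
#'   attention read-out).
#' @param attention Attach channel-attention gates to every fold's
#'   model before training.
#' @return List with `aggregate` (summed confusion, mean metrics),
#'   `folds` (per-fold `metrics_report`s), `loss_logs`, `splits` and
#'   optionally `models`.
#' @export
cross_validate <- function(samples, cfg_model, cfg_train,
                           spec = mixup_spec(), keep_models = FALSE,
                           attention = FALSE) {
  labels <- cohort_labels(samples)
  if (any(vapply(samples, function(s) s$synthetic, logical(1))))
    stopf("cross_validate expects real samples only; augmentation is fold-internal")
  splits <- stratified_kfold(labels, cfg_train$k_folds, cfg_train$seed)
  folds <- list(); loss_logs <- list(); models <- list()
  confusion <- NULL
  for (f in seq_along(splits)) {
    tr <- samples[splits[[f]]$train]
    te <- samples[splits[[f]]$test]
    if (!is.null(spec)) {
      fold_spec <- spec
      fold_spec$seed <- derive_seed(spec$seed, f)
      tr <- balance_by_mixup(tr, fold_spec)
    }
    fold_cfg_train <- cfg_train
    fold_cfg_train$seed <- derive_seed(cfg_train$seed, 100L + f)
    model0 <- init_fusion_net(cfg_model,
                              seed = derive_seed(fold_cfg_train$seed, 1L))
    if (attention) model0 <- attach_attention(model0)
    fit <- train_fold(tr, cfg_model, fold_cfg_train, model = model0)
    stopifnot(!any(vapply(te, function(s) s$synthetic, logical(1))))
    rep <- evaluate(fit$model, te)
    rep$fold <- f
    folds[[f]] <- rep
    loss_logs[[f]] <- fit$loss_log
    if (keep_models) models[[f]] <- fit$model
    confusion <- if (is.null(confusion)) rep$confusion
                 else confusion + rep$confusion
  }
  per_mats <- lapply(folds, function(r)
    as.matrix(r$per_class[, c("accuracy", "precision", "recall", "f1",
                              "auc")]))
  per_mean <- Reduce(`+`, lapply(per_mats, function(m) {
    m[is.na(m)] <- 0; m
  })) / Reduce(`+`, lapply(per_mats, function(m) (!is.na(m)) * 1))
  per_class <- data.frame(class = gait_classes(), per_mean)
  macro_names <- c("accuracy", "precision", "recall", "f1", "auc")
  macro <- lapply(macro_names, function(nm)
    mean(vapply(folds, function(r) r$macro[[nm]], numeric(1))))
  names(macro) <- macro_names
  aggregate <- list(
    confusion = confusion,
    per_class = per_class,
    macro = macro,
    overall_accuracy = sum(diag(confusion)) / sum(confusion),
    mean_fold_accuracy = mean(vapply(folds, function(r)
      r$overall_accuracy, numeric(1))))
  out <- list(aggregate = aggregate, folds = folds,
              loss_logs = loss_logs, splits = splits)
  if (keep_models) out$models <- models
  out
}
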