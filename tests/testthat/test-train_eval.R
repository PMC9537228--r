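bench_labels <- rep(gait_classes(), c(10, 4, 18, 13))

test_that("stratified folds partition 45 samples into test folds of 9", {
  expect_warning(splits <- stratified_kfold(bench_labels, 5, seed = 2),
                 "joint_problem")
  expect_length(splits, 5)
  tests <- lapply(splits, `[[`, "test")
  expect_true(all(lengths(tests) == 9))
  all_test <- sort(unlist(tests))
  expect_equal(all_test, 1:45)                 # partition, no overlap
  for (s in splits) {
    expect_equal(sort(c(s$train, s$test)), 1:45)
    expect_length(intersect(s$train, s$test), 0)
  }
  # determinism
  expect_identical(suppressWarnings(stratified_kfold(bench_labels, 5, 2)),
                   suppressWarnings(stratified_kfold(bench_labels, 5, 2)))
  expect_error(stratified_kfold(bench_labels, 1), "k must")
  expect_error(stratified_kfold(bench_labels, 46), "k must")
})

test_that("fold class proportions are as even as integers allow", {
  splits <- suppressWarnings(stratified_kfold(bench_labels, 5, seed = 4))
  for (cl in gait_classes()) {
    per_fold <- vapply(splits, function(s)
      sum(bench_labels[s$test] == cl), integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("metrics_report matches hand arithmetic and brute force", {
  # toy binary confusion [[9,1],[2,8]] embedded in two classes
  y <- c(rep("healthy", 10), rep("joint_problem", 10))
  pr <- matrix(0, 20, 4, dimnames = list(NULL, gait_classes()))
  pr[1:9, "healthy"] <- 1                       # 9 correct class 1
  pr[10, "joint_problem"] <- 1                  # 1 miss
  pr[11:12, "healthy"] <- 1                     # 2 misses class 2
  pr[13:20, "joint_problem"] <- 1
  pr[pr == 0] <- 1e-9; pr <- pr / rowSums(pr)
  rep <- suppressWarnings(metrics_report(y, pr))
  expect_equal(rep$confusion["healthy", "healthy"], 9)
  expect_equal(rep$per_class$recall[1], 0.9)
  expect_equal(rep$per_class$precision[1], 9 / 11, tolerance = 1e-12)
  expect_equal(rep$overall_accuracy, 17 / 20)

  # brute-force oracle on random multiclass predictions
  set.seed(31)
  n <- 60
  y2 <- sample(gait_classes(), n, replace = TRUE)
  p2 <- matrix(rexp(n * 4), n, 4, dimnames = list(NULL, gait_classes()))
  p2 <- p2 / rowSums(p2)
  rep2 <- suppressWarnings(metrics_report(y2, p2))
  pred2 <- gait_classes()[max.col(p2, ties.method = "first")]
  for (e in 1:4) {
    cl <- gait_classes()[e]
    prf <- brute_prf(y2, pred2, cl)
    expect_equal(rep2$per_class$precision[e], unname(prf["precision"]))
    expect_equal(rep2$per_class$recall[e], unname(prf["recall"]))
    expect_equal(rep2$per_class$f1[e], unname(prf["f1"]))
    expect_equal(rep2$per_class$auc[e],
                 brute_auc(p2[, e], y2 == cl), tolerance = 1e-12)
  }
})

test_that("ROC/AUC behave on closed-form and permutation cases", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  expect_equal(auc(c(1, 0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  rc <- roc_curve(c(0.9, 0.1), c(TRUE, FALSE))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[nrow(rc)], 1)
  # label-independent scores give AUC ~ 0.5
  set.seed(5)
  sc <- runif(4000); lab <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  expect_equal(auc(sc, lab), 0.5, tolerance = 0.05)
  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "ROC undefined")
})

test_that("macro accuracy and overall accuracy differ on imbalanced sets", {
  y <- c(rep("healthy", 9), "joint_problem")
  pr <- matrix(1e-9, 10, 4, dimnames = list(NULL, gait_classes()))
  pr[1:9, "healthy"] <- 1
  pr[10, "healthy"] <- 1                        # the rare class is missed
  pr <- pr / rowSums(pr)
  rep <- suppressWarnings(metrics_report(y, pr))
  expect_equal(rep$overall_accuracy, 0.9)
  # one-vs-rest accuracies: healthy 0.9, joint_problem 0.9, others 1.0
  expect_equal(rep$macro$accuracy, mean(c(0.9, 0.9, 1, 1)))
  expect_false(isTRUE(all.equal(rep$macro$recall, rep$overall_accuracy)))
})

test_that("train_fold logs, converges and is reproducible", {
  counts <- c(healthy = 3, joint_problem = 3, muscle_weakness = 3,
              neurological_defect = 3)
  co <- strong_cohort(counts, seed = 17, T_target = 20)
  cfg <- fusion_net_config(T_target = 20L, post_fusion_channels = c(4L, 6L))
  tc1 <- train_config(epochs = 1, batch_size = 6, seed = 3)
  fit1 <- train_fold(co, cfg, tc1)
  expect_length(fit1$loss_log, 1)

  tc <- train_config(epochs = 30, batch_size = 6, seed = 3)
  fit <- train_fold(co, cfg, tc)
  expect_lt(fit$loss_log[30], fit$loss_log[1])
  fit2 <- train_fold(co, cfg, tc)
  expect_identical(fit$model$params, fit2$model$params)
  expect_identical(fit$loss_log, fit2$loss_log)
})

test_that("evaluate yields a perfect report for a perfect classifier", {
  counts <- c(healthy = 4, joint_problem = 4, muscle_weakness = 4,
              neurological_defect = 4)
  co <- strong_cohort(counts, seed = 23, T_target = 20)
  cfg <- fusion_net_config(T_target = 20L, post_fusion_channels = c(8L, 8L))
  tc <- train_config(epochs = 50, batch_size = 8, seed = 5)
  fit <- train_fold(co, cfg, tc)
  rep <- evaluate(fit$model, co)               # train-set evaluation
  if (rep$overall_accuracy == 1) {
    expect_true(all(diag(rep$confusion) == 4))
    expect_true(all(rep$per_class$f1 == 1))
    expect_equal(rep$macro$accuracy, 1)
  }
  expect_equal(sum(rep$confusion), 16)
})

test_that("cross_validate keeps synthetic data out of test folds", {
  counts <- c(healthy = 4, joint_problem = 3, muscle_weakness = 4,
              neurological_defect = 4)
  co <- strong_cohort(counts, seed = 29, T_target = 15)
  cfg <- fusion_net_config(T_target = 15L, post_fusion_channels = c(3L, 4L))
  tc <- train_config(epochs = 2, batch_size = 8, k_folds = 3, seed = 7)
  spec <- mixup_spec(lam = 0.9, target_per_class = 4, seed = 7)
  cv <- suppressWarnings(cross_validate(co, cfg, tc, spec))
  expect_length(cv$folds, 3)
  expect_length(cv$loss_logs, 3)
  expect_true(all(vapply(cv$loss_logs, length, 1L) == 2))
  # every real sample tested exactly once
  expect_equal(sum(cv$aggregate$confusion), 15)
  tested <- sort(unlist(lapply(cv$splits, `[[`, "test")))
  expect_equal(tested, 1:15)
  # test folds index only real (non-synthetic) cohort members
  expect_true(all(!vapply(co, `[[`, TRUE, "synthetic")))
  # a cohort already containing synthetics is rejected
  aug <- balance_by_mixup(co, mixup_spec(target_per_class = 5, seed = 1))
  expect_error(cross_validate(aug, cfg, tc, spec), "real samples")
})
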