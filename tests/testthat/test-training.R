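test_that("training config defaults and validation", {
  tc <- scfp_train_config()
  expect_identical(tc$optimizer, "adam")
  expect_identical(tc$learning_rate, 0.01)
  expect_identical(tc$minibatch_size, 32L)
  expect_identical(tc$loss, "cross_entropy")
  expect_error(scfp_train_config(optimizer = "sgd"))
  expect_error(scfp_train_config(learning_rate = -1), "learning_rate")
})

test_that("ROC-AUC agrees with brute-force pairwise computation", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels <- c(labels[-(1:2)], 0, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_equal(roc_auc(labels, scores), brute_force_auc(labels, scores),
                 tolerance = 1e-12)
  }
  expect_identical(roc_auc(c(0, 1), c(0.1, 0.9)), 1)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "class")
})

test_that("stratified folds balance classes and cover every compound", {
  labels <- rep(c(1L, 0L), c(20L, 60L))
  f <- stratified_folds(labels, k = 5L, seed = 3L)
  expect_length(f, 80L)
  expect_identical(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_identical(sum(f == k & labels == 1L), 4L)
    expect_identical(sum(f == k & labels == 0L), 12L)
  }
  expect_identical(stratified_folds(labels, k = 5L, seed = 3L), f)
  expect_error(stratified_folds(c(1L, 0L, 0L, 0L), k = 3L), "fold")
})

test_that("a few epochs of training reduce loss and are reproducible", {
  d <- quick_dataset()
  fs <- featurize_dataset(d)
  cfg <- scfp_model_config(conv1_filters = 16L, conv2_filters = 8L,
                           hidden_units = 12L)
  tc <- scfp_train_config(epochs = 5L, seed = 7L)
  fit1 <- train_scfp(build_model(cfg, seed = 7L), fs, config = tc)
  fit2 <- train_scfp(build_model(cfg, seed = 7L), fs, config = tc)
  expect_identical(fit1$model$W1, fit2$model$W1)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_lt(fit1$history$loss[5], fit1$history$loss[1])
  expect_true(isTRUE(fit1$model$trained))
  expect_identical(nrow(fit1$history), 5L)
  # degenerate labels refuse to train
  fs_one <- subset_featurized(fs, which(d$label == 0L))
  expect_error(train_scfp(build_model(cfg, seed = 1L), fs_one, config = tc),
               "degenerate|single")
})

test_that("adagrad optimizer also trains", {
  d <- quick_dataset()
  fs <- featurize_dataset(d)
  cfg <- scfp_model_config(conv1_filters = 8L, conv2_filters = 4L,
                           hidden_units = 8L)
  tc <- scfp_train_config(optimizer = "adagrad", epochs = 4L, seed = 2L)
  fit <- train_scfp(build_model(cfg, seed = 2L), fs, config = tc)
  expect_lt(fit$history$loss[4], fit$history$loss[1])
})

test_that("cross_validate returns per-fold AUCs from held-out data", {
  d <- quick_dataset()
  cv <- cross_validate(d,
                       scfp_model_config(conv1_filters = 8L,
                                         conv2_filters = 4L,
                                         hidden_units = 8L),
                       scfp_train_config(epochs = 3L, seed = 5L),
                       k = 3L, seed = 5L)
  expect_length(cv$fold_auc, 3L)
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
  expect_equal(cv$mean_auc, mean(cv$fold_auc))
  expect_length(cv$folds, nrow(d))
})
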