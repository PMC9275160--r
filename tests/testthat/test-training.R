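test_that("joint training reduces the total loss and is reproducible", {
  sim <- tiny_sim(seed = 1)
  cfg <- tiny_config(seed = 2, epochs = 30)
  fit <- train_joint(sim$source, sim$target, cfg)
  expect_equal(nrow(fit$report$trace), 30L)
  expect_true(all(is.finite(as.matrix(fit$report$trace))))
  expect_lt(fit$report$trace$total[30], fit$report$trace$total[1])
  fit2 <- train_joint(sim$source, sim$target, cfg)
  expect_identical(fit$model, fit2$model)
})

test_that("target labels never leak into training", {
  sim <- tiny_sim(seed = 3)
  cfg <- tiny_config(seed = 4, epochs = 10)
  unlabeled_target <- sim$target
  unlabeled_target$labels <- NULL
  fit_lab <- train_joint(sim$source, sim$target, cfg)
  fit_unlab <- train_joint(sim$source, unlabeled_target, cfg)
  expect_identical(fit_lab$model, fit_unlab$model)
})

test_that("alpha = beta = 0 degenerates to a source-only classifier", {
  sim <- tiny_sim(seed = 5)
  cfg <- tiny_config(seed = 6, epochs = 10)
  cfg$weights <- loss_weights(0, 0, 1)
  fit <- train_joint(sim$source, sim$target, cfg)
  # swapping in a completely different target changes nothing
  other_target <- tiny_sim(seed = 99)$target
  fit_other <- train_joint(sim$source, other_target, cfg)
  expect_identical(fit$model, fit_other$model)
  # the discrimination trace is live, the calibration term inert
  expect_true(all(fit$report$trace$l_c == 0))
  expect_equal(fit$report$trace$total,
               fit$report$trace$l_d, tolerance = 1e-12)
})

test_that("gamma = 0 keeps the discrimination trace but freezes D", {
  sim <- tiny_sim(seed = 7)
  cfg <- tiny_config(seed = 8, epochs = 5)
  cfg$weights <- loss_weights(0.01, 20, 0)
  fit <- train_joint(sim$source, sim$target, cfg)
  expect_true(all(is.finite(fit$report$trace$l_d)))
  expect_equal(fit$report$trace$total,
               0.01 * fit$report$trace$l_r + 20 * fit$report$trace$l_c,
               tolerance = 1e-12)
  # discriminator affine parameters unchanged from initialization
  init <- init_model(ncol(sim$source$values),
                     seed = batchalign:::derive_seed(cfg$seed, 1L))
  expect_identical(fit$model$discriminator[[1]]$W, init$discriminator[[1]]$W)
})

test_that("training validates its inputs", {
  sim <- tiny_sim(seed = 9)
  cfg <- tiny_config(seed = 0, epochs = 2)
  short <- sim$target
  short$values <- short$values[, 1:5]
  short$feature_ids <- short$feature_ids[1:5]
  expect_error(train_joint(sim$source, short, cfg), "feature counts")
  unlabeled <- sim$source
  unlabeled$labels <- NULL
  expect_error(train_joint(unlabeled, sim$target, cfg), "labels")
  onecls <- sim$source
  onecls$labels <- rep(1L, length(onecls$labels))
  expect_error(train_joint(onecls, sim$target, cfg), "both classes")
})

test_that("prediction thresholds and row-permutation equivariance hold", {
  sim <- tiny_sim(seed = 10)
  fit <- train_joint(sim$source, sim$target, tiny_config(seed = 1, epochs = 20))
  pred <- predict(fit$model, sim$target)
  expect_true(all(pred$prob > 0 & pred$prob < 1))
  expect_identical(pred$label, as.integer(pred$prob >= 0.5))
  expect_identical(predict(fit$model, sim$target, threshold = 1 - 1e-9)$label,
                   as.integer(pred$prob >= 1 - 1e-9))
  # permuting rows permutes outputs identically
  set.seed(42)
  perm <- sample(nrow(sim$target$values))
  pred_perm <- predict(fit$model, sim$target$values[perm, ])
  expect_equal(pred_perm$prob, pred$prob[perm], tolerance = 1e-12)
})

test_that("prediction from thresholds: explicit boundary cases", {
  m <- init_model(3, seed = 0)
  X <- matrix(rnorm(15), 5, 3)
  p <- predict(m, X)$prob
  expect_identical(predict(m, X, threshold = 0.5)$label,
                   as.integer(p >= 0.5))
  expect_identical(predict(m, X, threshold = 1 - 1e-12)$label, rep(0L, 5))
})

test_that("stratified cross-validation pools held-out predictions", {
  sim <- tiny_sim(seed = 11, n_subjects = 40, class_effect = 3,
                  batch_shift = 0)
  cfg <- tiny_config(seed = 12, epochs = 80, minibatch_size = 16)
  rep2 <- in_batch_cross_validation(sim$source, folds = 2, cfg = cfg)
  preds <- attr(rep2, "predictions")
  expect_equal(nrow(preds), nrow(sim$source$values))
  expect_equal(sort(unique(preds$fold)), 1:2)
  # stratification balances folds to within one sample per class
  expect_lte(diff(range(table(preds$fold))), 2)
  # folds are stratified: class balance is preserved per fold
  tab <- table(preds$fold, preds$label)
  expect_true(max(abs(tab[1, ] - tab[2, ])) <= 1)
  # highly separable data with no batch effect -> high pooled accuracy
  expect_gte(rep2$acc, 0.9)
  # same seed, same fold assignment
  rep2b <- in_batch_cross_validation(sim$source, folds = 2, cfg = cfg)
  expect_identical(attr(rep2b, "predictions")$fold, preds$fold)
  expect_error(in_batch_cross_validation(sim$source, folds = 50, cfg = cfg),
               "stratification error")
})
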