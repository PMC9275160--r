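# Brute-force oracles for the classification metrics.
metrics_bruteforce <- function(y, p, thr = 0.5) {
  yhat <- as.integer(p >= thr)
  tp <- sum(y == 1 & yhat == 1); fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0); tn <- sum(y == 0 & yhat == 0)
  prec <- if (tp + fp == 0) NA else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA else tp / (tp + fn)
  f <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
       else 2 * prec * rec / (prec + rec)
  # AUC by enumerating every positive-negative pair
  pos <- p[y == 1]; neg <- p[y == 0]
  pairs <- 0; wins <- 0
  for (a in pos) for (b in neg) {
    pairs <- pairs + 1
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(acc = mean(y == yhat),
       f = f,
       auc = if (pairs == 0) NA_real_ else wins / pairs,
       mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom)
}

test_that("ACC/F/AUC/MCC match brute-force oracles on random vectors", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    p <- round(runif(n), 2)  # rounding forces ties to occur
    m <- classification_metrics(y, p)
    o <- metrics_bruteforce(y, p)
    expect_identical(m$acc, o$acc)
    expect_equal(m$f_score, o$f, tolerance = 1e-12)
    expect_equal(m$mcc, o$mcc, tolerance = 1e-12)
    expect_equal(m$auc, o$auc, tolerance = 1e-12)
  }
})

test_that("metric edge cases behave as documented", {
  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(c(m$acc, m$f_score, m$auc, m$mcc), c(1, 1, 1, 1))
  m2 <- classification_metrics(c(1, 0, 1, 0), c(0.6, 0.7, 0.8, 0.2))
  expect_equal(m2$acc, 0.75)
  expect_equal(m2$f_score, 0.8)
  expect_equal(m2$auc, 3 / 4)
  expect_equal(m2$mcc, 1 / sqrt(3))
  # all predictions one class -> MCC 0 by the zero-denominator convention
  expect_equal(classification_metrics(c(1, 0), c(0.9, 0.8))$mcc, 0)
  # single-class truth -> AUC flagged undefined, not a number
  m3 <- classification_metrics(c(1, 1), c(0.2, 0.9))
  expect_true(is.na(m3$auc))
  expect_false(m3$auc_defined)
  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
})

test_that("MCC is symmetric under class swap plus prediction inversion", {
  set.seed(22)
  for (rep in 1:20) {
    y <- rbinom(30, 1, 0.4)
    p <- runif(30)
    m1 <- classification_metrics(y, p)$mcc
    m2 <- classification_metrics(1 - y, 1 - p + 1e-9)$mcc
    expect_equal(m1, m2, tolerance = 1e-9)
  }
})

test_that("subsampled MMD protocol is seeded and detects shifts", {
  set.seed(23)
  A <- matrix(rnorm(400), 100, 4)
  # identical inputs, mean-L1 kernel: exactly zero (both sides keep all rows)
  est0 <- mmd_protocol(A, A, n_subsample = 200, n_repeats = 5,
                       kernel = kernel_config("linear_mean_l1"), seed = 1)
  expect_equal(est0$mean, 0)
  expect_equal(est0$std, 0)
  # reruns with the same seed are identical
  e1 <- mmd_protocol(A, A + 1, n_subsample = 50, n_repeats = 5, seed = 9)
  e2 <- mmd_protocol(A, A + 1, n_subsample = 50, n_repeats = 5, seed = 9)
  expect_identical(e1$values, e2$values)
  # monotone in the size of the shift
  shifts <- c(0, 0.5, 1, 2)
  means <- sapply(shifts, function(s)
    mmd_protocol(A, A + s, n_subsample = 80, n_repeats = 5, seed = 4)$mean)
  expect_true(all(diff(means) > 0))
  expect_error(mmd_protocol(A, A[, 1:2]), "share width")
})

test_that("between-batch MMD under the null matches the in-batch floor", {
  set.seed(24)
  A <- matrix(rnorm(2000 * 10), 2000, 10)
  B <- matrix(rnorm(2000 * 10), 2000, 10)
  between <- mmd_protocol(A, B, n_subsample = 200, n_repeats = 10, seed = 5)
  within <- in_batch_mmd(A, n_subsample = 200, n_repeats = 10, seed = 6)
  expect_lt(abs(between$mean - within$mean), 3 * max(between$std, within$std))
  # a shifted copy clearly exceeds the in-batch floor
  shifted <- mmd_protocol(A, B + 1, n_subsample = 200, n_repeats = 10, seed = 7)
  expect_gt(shifted$mean, within$mean)
})

test_that("in-batch MMD handles constant input and enforces minimum rows", {
  const <- matrix(1, 50, 3)
  expect_equal(in_batch_mmd(const, n_subsample = 10, n_repeats = 3,
                            kernel = kernel_config("linear_mean_l1"),
                            seed = 0)$mean, 0)
  expect_error(in_batch_mmd(matrix(1, 3, 2)), "at least 4 rows")
})

test_that("subject ensembling implements median-then-threshold", {
  expect_equal(ensemble_to_subject(c(0.9, 0.9, 0.1), rep("a", 3))$label, 1L)
  # even replicate count: median 0.5 labels 1 under the >= convention
  tie <- ensemble_to_subject(c(0.4, 0.6), c("a", "a"))
  expect_equal(tie$prob, 0.5)
  expect_equal(tie$label, 1L)
  # randomized replicate structures against a naive per-subject loop
  set.seed(25)
  for (rep in 1:10) {
    subj <- unlist(lapply(letters[1:3], function(s)
      rep(s, sample(1:5, 1))))
    probs <- runif(length(subj))
    out <- ensemble_to_subject(probs, subj)
    for (s in unique(subj)) {
      expect_equal(out$prob[out$subject == s],
                   median(probs[subj == s]))
      expect_equal(out$label[out$subject == s],
                   as.integer(median(probs[subj == s]) >= 0.5))
    }
    expect_identical(out$subject, sort(unique(subj)))
  }
  expect_error(ensemble_to_subject(c(NA, 1), c("a", "a")), "NA")
})

test_that("permutation test yields chance-level null accuracies", {
  sim <- tiny_sim(seed = 26, n_subjects = 40)
  cfg <- tiny_config(seed = 27, epochs = 8)
  res <- permutation_test(sim$source, sim$target, cfg, n_permutations = 5)
  expect_length(res$acc, 5)
  expect_true(all(res$acc >= 0 & res$acc <= 1))
  expect_equal(sum(res$histogram$count), 5)
  res2 <- permutation_test(sim$source, sim$target, cfg, n_permutations = 5)
  expect_identical(res$acc, res2$acc)
})

test_that("joint embedding concatenates rows with provenance", {
  set.seed(28)
  A <- matrix(rnorm(500), 50, 10)
  B <- matrix(rnorm(500, 2), 50, 10)
  emb <- export_embedding(list(A, B), batch_tags = c("b1", "b2"),
                          labels = list(rep(1L, 50), rep(0L, 50)),
                          stages = c("raw", "raw"))
  expect_equal(nrow(emb), 100)
  expect_equal(names(emb), c("x", "y", "batch", "label", "stage"))
  expect_equal(as.vector(table(emb$batch)), c(50, 50))
  expect_true(all(emb$label[emb$batch == "b1"] == 1))
  expect_error(export_embedding(list(A, B[, 1:3]), c("a", "b")),
               "share width")
  # mds method also returns one 2-D row per input row
  emb_mds <- export_embedding(list(A[1:10, ], B[1:10, ]), c("b1", "b2"),
                              method = "mds")
  expect_equal(nrow(emb_mds), 20)
})
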