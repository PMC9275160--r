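# Brute-force oracle for the biased/unbiased squared-MMD estimator: a naive
# double loop over all kernel pairs, evaluated per bandwidth and averaged.
mmd2_bruteforce <- function(Z1, Z2, multipliers, unbiased = FALSE) {
  gauss <- function(x, y, s2) exp(-sum((x - y)^2) / s2)
  Z <- rbind(Z1, Z2)
  d2 <- as.matrix(dist(Z))^2
  h2 <- median(d2[upper.tri(d2)])
  n1 <- nrow(Z1); n2 <- nrow(Z2)
  vals <- sapply(multipliers, function(m) {
    s2 <- h2 * m^2
    kxx <- kyy <- kxy <- 0
    for (i in seq_len(n1)) for (j in seq_len(n1))
      if (!unbiased || i != j) kxx <- kxx + gauss(Z1[i, ], Z1[j, ], s2)
    for (i in seq_len(n2)) for (j in seq_len(n2))
      if (!unbiased || i != j) kyy <- kyy + gauss(Z2[i, ], Z2[j, ], s2)
    for (i in seq_len(n1)) for (j in seq_len(n2))
      kxy <- kxy + gauss(Z1[i, ], Z2[j, ], s2)
    den1 <- if (unbiased) n1 * (n1 - 1) else n1^2
    den2 <- if (unbiased) n2 * (n2 - 1) else n2^2
    kxx / den1 + kyy / den2 - 2 * kxy / (n1 * n2)
  })
  max(mean(vals), 0)
}

test_that("vectorized Gaussian MMD equals the double-loop oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(3:50, 1); n2 <- sample(3:50, 1); d <- sample(1:10, 1)
    Z1 <- matrix(rnorm(n1 * d), n1, d)
    Z2 <- matrix(rnorm(n2 * d, mean = rep %% 3), n2, d)
    kc <- kernel_config()
    expect_equal(calibration_loss(Z1, Z2, kc),
                 mmd2_bruteforce(Z1, Z2, kc$bandwidth_multipliers),
                 tolerance = 1e-10)
  }
  # unbiased estimator against the same oracle
  Z1 <- matrix(rnorm(60), 20, 3); Z2 <- matrix(rnorm(60, 1), 20, 3)
  kc_u <- kernel_config(estimator = "unbiased")
  expect_equal(calibration_loss(Z1, Z2, kc_u),
               mmd2_bruteforce(Z1, Z2, kc_u$bandwidth_multipliers, TRUE),
               tolerance = 1e-10)
})

test_that("calibration loss contracts: identity, symmetry, permutation", {
  set.seed(3)
  Z1 <- matrix(rnorm(30), 10, 3)
  Z2 <- matrix(rnorm(30, 2), 10, 3)
  lin <- kernel_config("linear_mean_l1")
  expect_equal(calibration_loss(Z1, Z1, lin), 0)
  expect_equal(calibration_loss(Z1, Z1, kernel_config()), 0, tolerance = 1e-12)
  for (kc in list(kernel_config(), lin)) {
    expect_equal(calibration_loss(Z1, Z2, kc), calibration_loss(Z2, Z1, kc))
    expect_gte(calibration_loss(Z1, Z2, kc), 0)
    expect_equal(calibration_loss(Z1[sample(10), ], Z2[sample(10), ], kc),
                 calibration_loss(Z1, Z2, kc), tolerance = 1e-12)
  }
  # single-point means: L1 distance of column means
  expect_equal(calibration_loss(matrix(c(0, 0), 1), matrix(c(3, 4), 1), lin), 7)
  # translating both batches leaves the mean-L1 loss unchanged
  shift <- matrix(5, 10, 3)
  expect_equal(calibration_loss(Z1 + shift, Z2 + shift, lin),
               calibration_loss(Z1, Z2, lin), tolerance = 1e-12)
  expect_error(calibration_loss(Z1, Z2[, 1:2]), "share width")
  expect_error(calibration_loss(Z1[1, , drop = FALSE], Z2), "at least 2 rows")
})

test_that("MMD gradients match central finite differences", {
  set.seed(5)
  Z1 <- matrix(rnorm(12), 4, 3)
  Z2 <- matrix(rnorm(15, 1), 5, 3)
  # a fixed bandwidth isolates the kernel gradient from the (intentionally
  # non-differentiated) median heuristic
  h <- 1e-6
  for (kc in list(kernel_config(base_bandwidth2 = 2),
                  kernel_config(estimator = "unbiased", base_bandwidth2 = 2))) {
    g <- batchalign:::calibration_loss_grad(Z1, Z2, kc)
    for (probe in list(c(1, 2), c(3, 1), c(4, 3))) {
      Zp <- Z1; Zm <- Z1
      Zp[probe[1], probe[2]] <- Zp[probe[1], probe[2]] + h
      Zm[probe[1], probe[2]] <- Zm[probe[1], probe[2]] - h
      fd <- (calibration_loss(Zp, Z2, kc) - calibration_loss(Zm, Z2, kc)) / (2 * h)
      expect_equal(g$dZ1[probe[1], probe[2]], fd, tolerance = 1e-5)
      Wp <- Z2; Wm <- Z2
      Wp[probe[1], probe[2]] <- Wp[probe[1], probe[2]] + h
      Wm[probe[1], probe[2]] <- Wm[probe[1], probe[2]] - h
      fd2 <- (calibration_loss(Z1, Wp, kc) - calibration_loss(Z1, Wm, kc)) / (2 * h)
      expect_equal(g$dZ2[probe[1], probe[2]], fd2, tolerance = 1e-5)
    }
  }
  # the mean-L1 kind has an exact subgradient away from ties
  kc <- kernel_config("linear_mean_l1")
  g <- batchalign:::calibration_loss_grad(Z1, Z2, kc)
  fd <- (calibration_loss(Z1 + matrix(c(h, rep(0, 11)), 4, 3), Z2, kc) -
         calibration_loss(Z1 - matrix(c(h, rep(0, 11)), 4, 3), Z2, kc)) / (2 * h)
  expect_equal(g$dZ1[1, 1], fd, tolerance = 1e-6)
})

test_that("reconstruction loss equals the per-sample squared residual", {
  expect_equal(reconstruction_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(reconstruction_loss(matrix(c(1, 2), 1), matrix(c(0, 0), 1)), 5)
  set.seed(8)
  X <- matrix(rnorm(28), 7, 4); Xp <- matrix(rnorm(28), 7, 4)
  loop <- mean(sapply(seq_len(7), function(i) sum((X[i, ] - Xp[i, ])^2)))
  expect_equal(reconstruction_loss(X, Xp), loop, tolerance = 1e-12)
  expect_error(reconstruction_loss(X, Xp[, 1:2]), "identical shapes")
})

test_that("binary cross entropy has its closed-form values and guards", {
  expect_equal(discrimination_loss(0.5, 1), log(2))
  expect_equal(discrimination_loss(c(0.9, 0.1), c(1, 0)),
               -(log(0.9) + log(0.9)) / 2)
  expect_lt(discrimination_loss(c(1 - 1e-12, 1e-12), c(1, 0)), 1e-10)
  expect_equal(discrimination_loss(c(0.25, 0.5), c(1, 1), one_sided = TRUE),
               mean(-log(c(0.25, 0.5))))
  expect_error(discrimination_loss(c(0, 0.5), c(0, 1)), "strictly inside")
  expect_error(discrimination_loss(0.5, 2), "binary")
  expect_error(discrimination_loss(c(0.5, 0.5), 1), "equal length")
})

test_that("total loss is the weighted sum and linear in each component", {
  expect_equal(total_loss(1, 1, 1, loss_weights(1, 1, 1)), 3)
  expect_equal(total_loss(2, 3, 4, loss_weights(0.5, 1, 2)), 12)
  expect_equal(total_loss(7, 9, 4, loss_weights(0, 0, 1)), 4)
  w <- loss_weights(0.3, 0.7, 1.1)
  expect_equal(total_loss(2 * 5, 3, 4, w) - total_loss(5, 3, 4, w),
               0.3 * 5)
  expect_error(total_loss(Inf, 1, 1, w), "finite")
  expect_error(loss_weights(0, 0, 0), "strictly positive")
  expect_error(loss_weights(-1, 1, 1), "nonnegative")
})
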