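#' Loss weights for the joint objective
#'
#' The joint objective is `L = alpha * L_R + beta * L_C + gamma * L_D`:
#' reconstruction, calibration (MMD) and discrimination terms with
#' nonnegative scalar weights.
#'
#' @param alpha reconstruction weight.
#' @param beta calibration (MMD) weight.
#' @param gamma discrimination weight.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 1, gamma = 1) {
  for (w in list(alpha, beta, gamma))
    if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
      abort_ba("loss weights must be finite nonnegative scalars")
  if (alpha == 0 && beta == 0 && gamma == 0)
    abort_ba("at least one loss weight must be strictly positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' Kernel configuration for the calibration (MMD) loss
#'
#' Two readings of the latent-divergence loss are provided:
#'
#' * `multiscale_gaussian` (default) — the biased (V-statistic) squared-MMD
#'   estimator under a sum of Gaussian kernels whose bandwidths are the
#'   median heuristic of the pooled pairwise distances times
#'   `bandwidth_multipliers` (the multiscale sum is sensitive to mismatches
#'   both finer and coarser than the median distance). This is the training
#'   default; the V-statistic
#'   is preferred for optimization stability, the U-statistic is available
#'   via `estimator = "unbiased"` for evaluation parity studies.
#' * `linear_mean_l1` — the L1 distance between the two latent column-mean
#'   vectors, i.e. a per-feature first-moment divergence aggregated over
#'   samples. It is cheap and interpretable but blind to any distribution
#'   difference beyond the mean.
#'
#' @param kind `"multiscale_gaussian"` or `"linear_mean_l1"`.
#' @param bandwidth_multipliers positive multipliers applied to the
#'   median-heuristic base bandwidth (Gaussian kind only; default
#'   `{0.25, 0.5, 1, 2, 4}`).
#' @param estimator `"biased"` (V-statistic, default) or `"unbiased"`
#'   (U-statistic; Gaussian kind only).
#' @param base_bandwidth2 optional positive squared base bandwidth replacing
#'   the per-call median heuristic (the kernel is
#'   `exp(-d^2 / (m^2 * base_bandwidth2))` for each multiplier `m`). Useful
#'   when estimates must be comparable across calls or differentiable
#'   checks require a data-independent bandwidth; `NULL` (default) uses the
#'   median heuristic.
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(kind = c("multiscale_gaussian", "linear_mean_l1"),
                          bandwidth_multipliers = c(0.25, 0.5, 1, 2, 4),
                          estimator = c("biased", "unbiased"),
                          base_bandwidth2 = NULL) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  if (any(!is.finite(bandwidth_multipliers)) || any(bandwidth_multipliers <= 0))
    abort_ba("bandwidth multipliers must be positive")
  if (!is.null(base_bandwidth2) &&
      (!is.numeric(base_bandwidth2) || base_bandwidth2 <= 0))
    abort_ba("base_bandwidth2 must be positive when given")
  structure(list(kind = kind,
                 bandwidth_multipliers = as.numeric(bandwidth_multipliers),
                 estimator = estimator,
                 base_bandwidth2 = base_bandwidth2),
            class = "kernel_config")
}

# Squared Euclidean distance matrix between rows of A and rows of B.
pdist2 <- function(A, B) {
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Median-heuristic base squared bandwidth (2 * sigma^2 scale) from pooled
# pairwise squared distances; falls back to 1 for degenerate all-equal input.
median_bandwidth2 <- function(Z1, Z2) {
  Z <- rbind(Z1, Z2)
  d2 <- pdist2(Z, Z)
  d2 <- d2[upper.tri(d2)]
  m <- stats::median(d2)
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Calibration loss: divergence between two latent batches
#'
#' For the Gaussian kind this is the squared maximum mean discrepancy
#' estimated over the configured bandwidths and clipped at zero; for the
#' `linear_mean_l1` kind it is the L1 distance between the column means.
#' Symmetric in its two arguments and invariant to row permutations.
#'
#' @param Z1,Z2 latent matrices with a common number of columns. The Gaussian
#'   estimator requires at least 2 rows on each side.
#' @param kernel a [kernel_config()].
#' @return A nonnegative scalar.
#' @export
calibration_loss <- function(Z1, Z2, kernel = kernel_config()) {
  calibration_loss_grad(Z1, Z2, kernel, want_grad = FALSE)$loss
}

# Loss plus gradients with respect to Z1 and Z2 (bandwidths treated as
# constants: the median heuristic is recomputed per call but not
# differentiated through, which is standard practice).
calibration_loss_grad <- function(Z1, Z2, kernel = kernel_config(),
                                  want_grad = TRUE) {
  stopifnot(inherits(kernel, "kernel_config"))
  Z1 <- check_matrix(Z1, "Z1"); Z2 <- check_matrix(Z2, "Z2")
  if (ncol(Z1) != ncol(Z2))
    abort_ba("Z1 and Z2 must share width (%d vs %d)", ncol(Z1), ncol(Z2))
  n1 <- nrow(Z1); n2 <- nrow(Z2)
  if (kernel$kind == "linear_mean_l1") {
    diff <- colMeans(Z1) - colMeans(Z2)
    loss <- sum(abs(diff))
    if (!want_grad) return(list(loss = loss))
    s <- sign(diff)
    return(list(loss = loss,
                dZ1 = matrix(s / n1, n1, length(s), byrow = TRUE),
                dZ2 = matrix(-s / n2, n2, length(s), byrow = TRUE)))
  }
  if (n1 < 2L || n2 < 2L)
    abort_ba("the Gaussian MMD estimator needs at least 2 rows per batch")
  h2 <- kernel$base_bandwidth2 %||% median_bandwidth2(Z1, Z2)
  D11 <- pdist2(Z1, Z1); D22 <- pdist2(Z2, Z2); D12 <- pdist2(Z1, Z2)
  loss <- 0
  if (want_grad) { dZ1 <- Z1 * 0; dZ2 <- Z2 * 0 }
  unbiased <- kernel$estimator == "unbiased"
  for (m in kernel$bandwidth_multipliers) {
    s2 <- h2 * m * m  # kernel exp(-d^2 / s2), i.e. 2*sigma^2 = s2
    K11 <- exp(-D11 / s2); K22 <- exp(-D22 / s2); K12 <- exp(-D12 / s2)
    if (unbiased) {
      t11 <- (sum(K11) - n1) / (n1 * (n1 - 1))
      t22 <- (sum(K22) - n2) / (n2 * (n2 - 1))
    } else {
      t11 <- mean(K11); t22 <- mean(K22)
    }
    loss <- loss + t11 + t22 - 2 * mean(K12)
    if (want_grad) {
      # d k(x, y) / d x = k * 2 * (y - x) / s2
      if (unbiased) { diag(K11) <- 0; diag(K22) <- 0 }
      c11 <- if (unbiased) 1 / (n1 * (n1 - 1)) else 1 / (n1 * n1)
      c22 <- if (unbiased) 1 / (n2 * (n2 - 1)) else 1 / (n2 * n2)
      c12 <- 1 / (n1 * n2)
      dZ1 <- dZ1 + (4 * c11 / s2) * (K11 %*% Z1 - rowSums(K11) * Z1) -
        (4 * c12 / s2) * (K12 %*% Z2 - rowSums(K12) * Z1)
      dZ2 <- dZ2 + (4 * c22 / s2) * (K22 %*% Z2 - rowSums(K22) * Z2) -
        (4 * c12 / s2) * (crossprod(K12, Z1) - colSums(K12) * Z2)
    }
  }
  nb <- length(kernel$bandwidth_multipliers)
  loss <- max(loss / nb, 0)
  if (!want_grad) return(list(loss = loss))
  list(loss = loss, dZ1 = dZ1 / nb, dZ2 = dZ2 / nb)
}

#' Reconstruction loss
#'
#' Mean over samples of the squared Euclidean norm of the residual between
#' each input row and its reconstruction.
#'
#' @param X input matrix (prior to calibration).
#' @param X_prime reconstructed matrix of identical shape.
#' @return A nonnegative scalar, zero iff `X == X_prime`.
#' @export
reconstruction_loss <- function(X, X_prime) {
  X <- check_matrix(X, "X"); X_prime <- check_matrix(X_prime, "X_prime")
  if (!identical(dim(X), dim(X_prime)))
    abort_ba("X and X_prime must have identical shapes")
  sum((X - X_prime)^2) / nrow(X)
}

#' Discrimination loss (binary cross entropy)
#'
#' Mean over samples of `-[y log p + (1 - y) log(1 - p)]`. The one-sided
#' variant `-y log p` (positive-class term only) is available for audit; it
#' cannot by itself train a binary classifier, since negative samples
#' contribute no gradient.
#'
#' @param p predicted class-1 probabilities, strictly inside (0, 1); values
#'   outside are an error (clamp upstream if needed).
#' @param y binary labels in `{0, 1}`.
#' @param one_sided use the positive-class term only (default `FALSE`).
#' @return A nonnegative scalar.
#' @export
discrimination_loss <- function(p, y, one_sided = FALSE) {
  if (length(p) != length(y))
    abort_ba("p and y must have equal length (%d vs %d)", length(p), length(y))
  if (length(p) == 0L) abort_ba("empty input")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    abort_ba("probabilities must lie strictly inside (0, 1)")
  if (!all(y %in% c(0, 1))) abort_ba("labels must be binary 0/1")
  if (one_sided) mean(-y * log(p))
  else mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Weighted total loss
#'
#' @param lr,lc,ld finite component losses (reconstruction, calibration,
#'   discrimination).
#' @param w a [loss_weights()].
#' @return `alpha * lr + beta * lc + gamma * ld`.
#' @export
total_loss <- function(lr, lc, ld, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  vals <- c(lr, lc, ld)
  if (length(vals) != 3L || any(!is.finite(vals)))
    abort_ba("component losses must be finite scalars")
  w$alpha * lr + w$beta * lc + w$gamma * ld
}
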