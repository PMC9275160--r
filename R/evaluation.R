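#' Subsampled MMD between two sample matrices
#'
#' Each repeat draws `n_subsample` rows from each side without replacement
#' and computes the kernel MMD between the draws; a side with at most
#' `n_subsample` rows contributes all of its rows (resampling an already
#' complete side would only add noise). The protocol reports the mean and
#' standard deviation over repeats. For the Gaussian kernel the reported value is the square root of
#' the clipped squared-MMD estimate, i.e. an MMD on the scale of the kernel
#' embedding distance.
#'
#' @param A,B numeric matrices sharing a column count.
#' @param n_subsample rows drawn per side per repeat (default 500).
#' @param n_repeats number of independent subsample draws (default 10).
#' @param kernel a [kernel_config()].
#' @param seed integer seed; the protocol is deterministic given the seed.
#' @return An object of class `mmd_estimate` with fields `mean`, `std`,
#'   `values`, `n_subsample`, `n_repeats`, `seed`.
#' @export
mmd_protocol <- function(A, B, n_subsample = 500L, n_repeats = 10L,
                         kernel = kernel_config(), seed = 0L) {
  A <- check_matrix(A, "A"); B <- check_matrix(B, "B")
  if (ncol(A) != ncol(B))
    abort_ba("A and B must share width (%d vs %d)", ncol(A), ncol(B))
  if (n_repeats < 1L) abort_ba("n_repeats must be >= 1")
  vals <- with_seed(seed, {
    draw <- function(n) if (n <= n_subsample) seq_len(n)
                        else sample.int(n, n_subsample)
    vapply(seq_len(n_repeats), function(r) {
      mmd_value(A[draw(nrow(A)), , drop = FALSE],
                B[draw(nrow(B)), , drop = FALSE], kernel)
    }, numeric(1))
  })
  new_mmd_estimate(vals, n_subsample, n_repeats, seed)
}

mmd_value <- function(A, B, kernel) {
  v <- calibration_loss(A, B, kernel)
  if (kernel$kind == "multiscale_gaussian") sqrt(max(v, 0)) else v
}

new_mmd_estimate <- function(vals, n_subsample, n_repeats, seed) {
  structure(list(mean = mean(vals),
                 std = if (length(vals) > 1L) stats::sd(vals) else 0,
                 values = vals,
                 n_subsample = as.integer(n_subsample),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "mmd_estimate")
}

#' @export
print.mmd_estimate <- function(x, ...) {
  cat(sprintf("<mmd_estimate> %.4f +/- %.4f (n_subsample = %d, repeats = %d)\n",
              x$mean, x$std, x$n_subsample, x$n_repeats))
  invisible(x)
}

#' In-batch MMD: the empirical floor of the between-batch measure
#'
#' Each repeat splits the rows of `A` at random into two disjoint halves
#' (each capped at `n_subsample` rows) and computes their MMD. Since no batch
#' effect exists inside one batch, this estimates the lower bound that a
#' perfect batch-effect correction could reach.
#'
#' @inheritParams mmd_protocol
#' @param A numeric matrix with at least 4 rows.
#' @return An `mmd_estimate`.
#' @export
in_batch_mmd <- function(A, n_subsample = 500L, n_repeats = 10L,
                         kernel = kernel_config(), seed = 0L) {
  A <- check_matrix(A, "A")
  n <- nrow(A)
  if (n < 4L) abort_ba("in-batch MMD needs at least 4 rows, got %d", n)
  half <- n %/% 2L
  take <- min(half, n_subsample)
  vals <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      perm <- sample.int(n)
      mmd_value(A[perm[seq_len(take)], , drop = FALSE],
                A[perm[(half + 1L):(half + take)], , drop = FALSE], kernel)
    }, numeric(1))
  })
  new_mmd_estimate(vals, take, n_repeats, seed)
}

new_metrics_report <- function(acc, f_score, auc, mcc, n, level) {
  structure(list(acc = acc, f_score = f_score, auc = auc, mcc = mcc,
                 n = as.integer(n), level = level),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> [%s level, n = %d] ACC %.3f | F %.3f | AUC %s | MCC %.3f\n",
              x$level, x$n, x$acc, x$f_score,
              if (is.na(x$auc)) "undefined" else sprintf("%.3f", x$auc), x$mcc))
  invisible(x)
}

#' Binary classification metrics: ACC, F-score, AUC, MCC
#'
#' * ACC — fraction of correct hard labels at `threshold` (label 1 iff
#'   `p >= threshold`).
#' * F-score — harmonic mean of precision and recall on class 1 (0 when
#'   precision or recall is undefined).
#' * AUC — probability that a random positive outscores a random negative,
#'   ties counted 1/2 (the rank / Mann-Whitney form, exact on small n).
#'   When `y_true` contains a single class the AUC is undefined and reported
#'   as `NA` with `auc_defined = FALSE`.
#' * MCC — Matthews correlation from the 2x2 confusion table, defined as 0
#'   when any marginal factor of the denominator is 0.
#'
#' @param y_true binary ground-truth vector in `{0, 1}`.
#' @param p numeric score/probability vector aligned to `y_true`.
#' @param threshold hard-label cutoff (default 0.5).
#' @param level metric level tag, `"sample"` or `"subject"`.
#' @return An object of class `metrics_report`.
#' @export
classification_metrics <- function(y_true, p, threshold = 0.5,
                                   level = c("sample", "subject")) {
  level <- match.arg(level)
  if (length(y_true) == 0L) abort_ba("empty input")
  if (length(y_true) != length(p))
    abort_ba("y_true and p must have equal length")
  if (!all(y_true %in% c(0, 1))) abort_ba("y_true must be binary 0/1")
  if (anyNA(p)) abort_ba("scores contain missing values")
  y <- as.integer(y_true)
  yhat <- as.integer(p >= threshold)
  tp <- as.numeric(sum(yhat == 1L & y == 1L))
  fp <- as.numeric(sum(yhat == 1L & y == 0L))
  fn <- as.numeric(sum(yhat == 0L & y == 1L))
  tn <- as.numeric(sum(yhat == 0L & y == 0L))
  acc <- (tp + tn) / length(y)
  f_score <- if ((2 * tp + fp + fn) == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  auc_defined <- n1 > 0L && n0 > 0L
  auc <- if (auc_defined) {
    r <- rank(p)  # average ranks give the ties-count-1/2 convention
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  out <- new_metrics_report(acc, f_score, auc, mcc, length(y), level)
  out$auc_defined <- auc_defined
  out
}

#' Ensemble replicate sample predictions to subject level
#'
#' A subject's probability is the median of its samples' probabilities; the
#' subject label is 1 iff that median is `>= threshold` (so an even-replicate
#' tie at exactly the threshold labels 1).
#'
#' @param sample_probs numeric probability vector, one per sample.
#' @param sample_subjects subject identifier per sample, aligned with
#'   `sample_probs`.
#' @param threshold decision cutoff (default 0.5).
#' @return A data frame with one row per subject, ordered by sorted subject
#'   identifier: columns `subject`, `prob` (median), `label`, `n_samples`.
#' @export
ensemble_to_subject <- function(sample_probs, sample_subjects,
                                threshold = 0.5) {
  if (length(sample_probs) != length(sample_subjects))
    abort_ba("probabilities and subject ids must have equal length")
  if (anyNA(sample_probs)) abort_ba("probabilities contain NA")
  subjects <- sort(unique(as.character(sample_subjects)))
  med <- vapply(subjects, function(s)
    stats::median(sample_probs[sample_subjects == s]), numeric(1))
  cnt <- vapply(subjects, function(s)
    sum(sample_subjects == s), integer(1))
  data.frame(subject = subjects, prob = as.numeric(med),
             label = as.integer(med >= threshold),
             n_samples = as.integer(cnt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label-permutation null for the cross-batch classifier
#'
#' Repeatedly shuffles the source labels, retrains the full joint pipeline
#' and records the target-batch accuracy, giving the null distribution of
#' accuracies attainable without genuine label information.
#'
#' @param source labeled [feature_table()].
#' @param target_with_labels labeled [feature_table()]; its labels are used
#'   only to score the permuted models.
#' @param cfg a [train_config()]; each permutation derives its own training
#'   seed from `cfg$seed`.
#' @param n_permutations number of label shuffles (default 100).
#' @param bins histogram bin breaks on `[0, 1]` (default width 0.05).
#' @return An object of class `permutation_result`: `acc` (one accuracy per
#'   permutation), `histogram` (data frame of bin edges and counts), `bins`.
#' @export
permutation_test <- function(source, target_with_labels, cfg = train_config(),
                             n_permutations = 100L,
                             bins = seq(0, 1, by = 0.05)) {
  validate_pair(source, target_with_labels)
  if (is.null(target_with_labels$labels))
    abort_ba("the target table must carry labels to score permutations")
  if (n_permutations < 1L) abort_ba("n_permutations must be >= 1")
  acc <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    perm_source <- source
    perm_source$labels <- with_seed(derive_seed(cfg$seed, 1000L + i),
                                    sample(source$labels))
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, 2000L + i)
    fit <- train_joint(perm_source, target_with_labels, cfg_i)
    pred <- predict(fit$model, target_with_labels,
                    threshold = cfg$decision_threshold)
    acc[i] <- mean(pred$label == target_with_labels$labels)
  }
  counts <- table(cut(acc, breaks = bins, include.lowest = TRUE))
  structure(list(acc = acc,
                 histogram = data.frame(bin_lo = utils::head(bins, -1),
                                        bin_hi = bins[-1],
                                        count = as.integer(counts)),
                 bins = bins),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations | null ACC mean %.3f, range [%.3f, %.3f]\n",
              length(x$acc), mean(x$acc), min(x$acc), max(x$acc)))
  invisible(x)
}

#' Joint 2-D embedding of several matrices for before/after visualization
#'
#' Concatenates all input matrices and fits one shared 2-D embedding, so raw
#' and calibrated data (or several batches) live on the same axes. The
#' coordinates, not pictures, are the contract: plotting is left to the
#' caller. Available methods are `"pca"` (principal components, default) and
#' `"mds"` (classical multidimensional scaling).
#'
#' @param matrices named or unnamed list of numeric matrices sharing a
#'   column count.
#' @param batch_tags batch tag per matrix (recycled to rows).
#' @param labels optional list of per-row label vectors (one per matrix), or
#'   `NULL`.
#' @param stages optional per-matrix stage tag (for example `"raw"` /
#'   `"calibrated"`).
#' @param method `"pca"` or `"mds"`.
#' @param seed kept for interface stability; both available methods are
#'   deterministic.
#' @return A data frame with columns `x`, `y`, `batch`, `label`, `stage`,
#'   one row per input row, in input order.
#' @export
export_embedding <- function(matrices, batch_tags, labels = NULL,
                             stages = NULL, method = c("pca", "mds"),
                             seed = 0L) {
  method <- match.arg(method)
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  matrices <- lapply(matrices, check_matrix, name = "matrices[[i]]")
  widths <- vapply(matrices, ncol, 1L)
  if (length(unique(widths)) != 1L)
    abort_ba("all matrices must share width, got: %s", toString(widths))
  if (length(batch_tags) != length(matrices))
    abort_ba("one batch tag per matrix is required")
  rows <- vapply(matrices, nrow, 1L)
  X <- do.call(rbind, matrices)
  coords <- switch(method,
    pca = stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)$x[, 1:2],
    mds = stats::cmdscale(stats::dist(X), k = 2L))
  lab <- if (is.null(labels)) rep(NA_integer_, sum(rows))
  else unlist(lapply(seq_along(matrices), function(i)
    labels[[i]] %||% rep(NA_integer_, rows[i])))
  data.frame(x = coords[, 1], y = coords[, 2],
             batch = rep(as.character(batch_tags), rows),
             label = lab,
             stage = rep(as.character(stages %||% rep("raw", length(matrices))),
                         rows),
             stringsAsFactors = FALSE, row.names = NULL)
}
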