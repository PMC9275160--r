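#' Sparse-selector specification for the biomarker screen
#'
#' The selection-frequency construction refits an embedded-sparsity linear
#' classifier on bootstrap resamples and counts how often each feature
#' receives a nonzero weight. The selector is an L1-penalized logistic
#' regression with the penalty chosen by inner cross-validation on each
#' bootstrap.
#'
#' @param lambda_choice `"lambda.1se"` (default; sparser, the conventional
#'   stability choice) or `"lambda.min"`.
#' @param nfolds inner cross-validation folds (default 5).
#' @return A list of class `selector_spec`.
#' @export
selector_spec <- function(lambda_choice = c("lambda.1se", "lambda.min"),
                          nfolds = 5L) {
  lambda_choice <- match.arg(lambda_choice)
  if (nfolds < 3L) abort_ba("nfolds must be >= 3")
  structure(list(lambda_choice = lambda_choice, nfolds = as.integer(nfolds)),
            class = "selector_spec")
}

#' Per-feature model-selection frequency under bootstrap resampling
#'
#' For each of `n_resamples` bootstrap draws of the samples, fits the sparse
#' selector and records which features enter the model; a feature's
#' selection frequency is its inclusion count divided by `n_resamples`.
#' Bootstrap draws that lose one class are redrawn (up to 25 retries).
#'
#' @param batch labeled [feature_table()].
#' @param n_resamples number of bootstrap resamples (default 100).
#' @param selector a [selector_spec()].
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return Named numeric vector of frequencies in `[0, 1]`, one per feature.
#' @export
selection_frequency <- function(batch, n_resamples = 100L,
                                selector = selector_spec(), seed = 0L) {
  stopifnot(inherits(batch, "feature_table"), inherits(selector, "selector_spec"))
  if (is.null(batch$labels)) abort_ba("selection frequency requires labels")
  if (length(unique(batch$labels)) < 2L) abort_ba("both classes must be present")
  if (n_resamples < 1L) abort_ba("n_resamples must be >= 1")
  X <- batch$values
  y <- batch$labels
  n <- nrow(X)
  counts <- with_seed(seed, {
    cnt <- numeric(ncol(X))
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- 0L
      while (length(unique(y[idx])) < 2L) {
        tries <- tries + 1L
        if (tries > 25L) abort_ba("could not draw a two-class bootstrap after 25 retries")
        idx <- sample.int(n, n, replace = TRUE)
      }
      fit <- glmnet::cv.glmnet(X[idx, , drop = FALSE], y[idx],
                               family = "binomial", alpha = 1,
                               nfolds = selector$nfolds)
      beta <- stats::coef(fit, s = selector$lambda_choice)[-1L, 1L]
      cnt <- cnt + (beta != 0)
    }
    cnt
  })
  stats::setNames(counts / n_resamples, batch$feature_ids)
}

#' Screen features for putative biomarkers
#'
#' Combines the bootstrap selection frequency with a per-feature two-sample
#' location test between the classes (Wilcoxon rank-sum by default, robust
#' for intensity data; Welch t as an alternative). A feature passes when its
#' selection frequency exceeds `freq_threshold` and its p-value is below
#' `p_threshold`. The p-values are deliberately not corrected for multiple
#' testing: the frequency filter is the primary screen and the raw-p cutoff
#' is its companion condition.
#'
#' @param batch labeled [feature_table()].
#' @param freq_threshold selection-frequency cutoff (default 0.9; strict
#'   `>` comparison).
#' @param p_threshold p-value cutoff (default 0.05; strict `<` comparison).
#' @param n_resamples bootstrap resamples for the frequency (default 100).
#' @param selector a [selector_spec()].
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param seed integer seed.
#' @return A data frame of class `biomarker_result` with one row per
#'   feature: `feature_id`, `selection_frequency`, `p_value`, `passes`.
#'   Candidates are the rows with `passes == TRUE`.
#' @export
screen_biomarkers <- function(batch, freq_threshold = 0.9, p_threshold = 0.05,
                              n_resamples = 100L, selector = selector_spec(),
                              test = c("wilcoxon", "t"), seed = 0L) {
  test <- match.arg(test)
  freq <- selection_frequency(batch, n_resamples, selector, seed)
  X <- batch$values
  y <- batch$labels
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    a <- X[y == 1L, j]; b <- X[y == 0L, j]
    if (test == "wilcoxon")
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    else
      stats::t.test(a, b)$p.value
  }, numeric(1))
  out <- data.frame(feature_id = batch$feature_ids,
                    selection_frequency = as.numeric(freq),
                    p_value = pvals,
                    passes = as.numeric(freq) > freq_threshold &
                      pvals < p_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("biomarker_result", "data.frame")
  out
}

#' Per-feature class summary backing biomarker boxplots
#'
#' @param batch labeled [feature_table()].
#' @param feature_ids features to summarize (default: all).
#' @return Data frame of per-feature, per-class median and quartiles.
#' @export
feature_class_summary <- function(batch, feature_ids = batch$feature_ids) {
  stopifnot(inherits(batch, "feature_table"))
  if (is.null(batch$labels)) abort_ba("class summary requires labels")
  idx <- match(feature_ids, batch$feature_ids)
  if (anyNA(idx)) abort_ba("unknown feature id: %s",
                           feature_ids[is.na(idx)][1L])
  do.call(rbind, lapply(idx, function(j) {
    do.call(rbind, lapply(c(0L, 1L), function(cl) {
      v <- batch$values[batch$labels == cl, j]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(feature_id = batch$feature_ids[j], class = cl,
                 q1 = q[1], median = q[2], q3 = q[3],
                 stringsAsFactors = FALSE)
    }))
  }))
}
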