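#' Configuration of the two-batch synthetic generator
#'
#' The generator emulates the structure of real two-batch feature-table
#' studies: a class-conditional signal shared by both batches, a
#' subject/replicate hierarchy (each subject contributes 1-5 replicate
#' samples, as is typical for repeated MS acquisitions), and a batch-specific
#' corruption of the target batch composed of per-feature additive shifts,
#' multiplicative scalings and a monotone nonlinear warp. The warp term
#' (`x + s * sin(x / tau)`) is deliberately outside the location-scale family
#' so that purely additive/multiplicative corrections cannot fully remove it.
#'
#' @param n_features number of features (25 emulates a CyTOF marker panel,
#'   814 a MALDI MS m/z-bin table).
#' @param n_subjects_per_batch subjects per batch.
#' @param replicates_per_subject integer scalar or `c(min, max)` range in
#'   `[1, 5]`; replicate counts are drawn uniformly from the range.
#' @param class_effect scalar magnitude of the mean shift on signal features
#'   (in noise-SD units), or a full per-feature shift vector.
#' @param signal_fraction fraction of features carrying class signal
#'   (ignored when `class_effect` is a vector).
#' @param batch_shift SD of the per-feature additive batch shift applied to
#'   the target batch.
#' @param batch_scale SD of the per-feature log-scale factor of the target
#'   batch (0 = no scaling; 0.3 means scale factors roughly in
#'   `exp(+-0.6)`).
#' @param nonlinear_warp strength `s` of the monotone warp
#'   `x + s * sin(x / tau)` applied to the target batch (with `tau = 2`,
#'   monotone for `s < 2`).
#' @param noise_sd SD of the i.i.d. replicate noise.
#' @param subject_sd SD of the per-subject, per-feature random effect.
#' @param class_balance probability that a subject is class 1.
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_features = 25, n_subjects_per_batch = 200,
                       replicates_per_subject = 1, class_effect = 1,
                       signal_fraction = 0.4, batch_shift = 1,
                       batch_scale = 0.2, nonlinear_warp = 0.5,
                       noise_sd = 1, subject_sd = 0.5, class_balance = 0.5,
                       seed = 0L) {
  stopifnot(n_features >= 1, n_subjects_per_batch >= 1)
  reps <- as.integer(replicates_per_subject)
  if (length(reps) == 1L) reps <- c(reps, reps)
  if (length(reps) != 2L || any(reps < 1L) || any(reps > 5L) || reps[1] > reps[2])
    abort_ba("replicates_per_subject must be a scalar or [min, max] range within [1, 5]")
  for (v in list(signal_fraction, class_balance))
    if (v < 0 || v > 1) abort_ba("fractions must lie in [0, 1]")
  for (v in list(batch_shift, batch_scale, nonlinear_warp, subject_sd))
    if (v < 0) abort_ba("effect magnitudes must be nonnegative")
  if (noise_sd <= 0) abort_ba("noise_sd must be positive")
  structure(list(n_features = as.integer(n_features),
                 n_subjects_per_batch = as.integer(n_subjects_per_batch),
                 replicates_per_subject = reps,
                 class_effect = class_effect,
                 signal_fraction = signal_fraction,
                 batch_shift = batch_shift, batch_scale = batch_scale,
                 nonlinear_warp = nonlinear_warp, noise_sd = noise_sd,
                 subject_sd = subject_sd, class_balance = class_balance,
                 seed = as.integer(seed)),
            class = "sim_config")
}

warp_tau <- 2

simulate_batch <- function(cfg, baseline, delta, batch_tag) {
  ns <- cfg$n_subjects_per_batch
  p <- cfg$n_features
  labels_subj <- stats::rbinom(ns, 1L, cfg$class_balance)
  reps <- if (cfg$replicates_per_subject[1] == cfg$replicates_per_subject[2])
    rep(cfg$replicates_per_subject[1], ns)
  else
    sample(seq(cfg$replicates_per_subject[1], cfg$replicates_per_subject[2]),
           ns, replace = TRUE)
  n <- sum(reps)
  X <- matrix(0, n, p)
  subj_ids <- character(n)
  samp_ids <- character(n)
  labels <- integer(n)
  row <- 0L
  for (s in seq_len(ns)) {
    profile <- baseline + labels_subj[s] * delta +
      stats::rnorm(p, 0, cfg$subject_sd)
    for (r in seq_len(reps[s])) {
      row <- row + 1L
      X[row, ] <- profile + stats::rnorm(p, 0, cfg$noise_sd)
      subj_ids[row] <- sprintf("%s_sub%04d", batch_tag, s)
      samp_ids[row] <- sprintf("%s_sub%04d_r%d", batch_tag, s, r)
      labels[row] <- labels_subj[s]
    }
  }
  list(X = X, subject_ids = subj_ids, sample_ids = samp_ids, labels = labels)
}

soft_clip_nonneg <- function(x) {
  # softplus: smooth for x near 0, identity for x >> 0; MS intensities are
  # nonnegative
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' Generate a two-batch synthetic dataset with known ground truth
#'
#' Both batches share the same class-conditional generative model; the
#' target batch is then corrupted feature-wise by
#' `x -> scale * (x + s * sin(x / tau)) + shift`. Both returned tables carry
#' labels (strip the target's labels before training; [train_joint()] also
#' ignores them).
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `source` and `target` ([feature_table()]s)
#'   and `truth` (signal feature indices, subject labels, and the per-feature
#'   batch transformation actually applied).
#' @export
generate_two_batches <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    p <- cfg$n_features
    baseline <- stats::runif(p, 3, 8)
    if (length(cfg$class_effect) == p) {
      delta <- as.numeric(cfg$class_effect)
      signal_idx <- which(delta != 0)
    } else {
      n_sig <- max(0L, round(cfg$signal_fraction * p))
      signal_idx <- sort(sample.int(p, n_sig))
      delta <- numeric(p)
      if (n_sig > 0)
        delta[signal_idx] <- cfg$class_effect *
          sample(c(-1, 1), n_sig, replace = TRUE)
    }
    b1 <- simulate_batch(cfg, baseline, delta, "b1")
    b2 <- simulate_batch(cfg, baseline, delta, "b2")
    shift <- stats::rnorm(p, 0, cfg$batch_shift)
    scale <- exp(stats::rnorm(p, 0, cfg$batch_scale))
    warp_s <- cfg$nonlinear_warp
    X2 <- b2$X + warp_s * sin(b2$X / warp_tau)
    X2 <- sweep(sweep(X2, 2L, scale, "*"), 2L, shift, "+")
    X1 <- soft_clip_nonneg(b1$X)
    X2 <- soft_clip_nonneg(X2)
    fid <- sprintf("f%03d", seq_len(p))
    source <- feature_table(X1, feature_ids = fid, sample_ids = b1$sample_ids,
                            subject_ids = b1$subject_ids, batch_id = "batch1",
                            labels = b1$labels)
    target <- feature_table(X2, feature_ids = fid, sample_ids = b2$sample_ids,
                            subject_ids = b2$subject_ids, batch_id = "batch2",
                            labels = b2$labels)
    truth <- list(signal_feature_indices = signal_idx,
                  class_shift = delta,
                  source_labels = b1$labels, target_labels = b2$labels,
                  batch_transform = list(shift = shift, scale = scale,
                                         warp_strength = warp_s,
                                         warp_tau = warp_tau))
    list(source = source, target = target, truth = truth)
  })
}

#' Named generator presets
#'
#' * `cytof_like` — 25 features, 1500 single-replicate subjects per batch:
#'   the scale and dimensionality of a mass-cytometry marker panel where
#'   every cell is a sample.
#' * `maldi_like` — 814 features, 200 subjects per batch with 5 replicate
#'   acquisitions each: the shape of a MALDI MS m/z-bin study.
#' * `cytof_small` — a 250-subject reduction of `cytof_like` for protocols
#'   that retrain many times (permutation nulls, cross-validation demos).
#' * `planted` — 100 features of which exactly 5 carry a strong class
#'   signal; intended for biomarker-screen recovery studies.
#'
#' @param seed seed stored in every preset (default 0).
#' @return Named list of [sim_config()] objects.
#' @export
presets <- function(seed = 0L) {
  list(
    cytof_like = sim_config(n_features = 25, n_subjects_per_batch = 1500,
                            replicates_per_subject = 1, class_effect = 1.2,
                            signal_fraction = 0.4, batch_shift = 1.2,
                            batch_scale = 0.3, nonlinear_warp = 0.8,
                            noise_sd = 1, subject_sd = 0.5, seed = seed),
    maldi_like = sim_config(n_features = 814, n_subjects_per_batch = 200,
                            replicates_per_subject = 5, class_effect = 0.8,
                            signal_fraction = 0.1, batch_shift = 1.2,
                            batch_scale = 0.3, nonlinear_warp = 0.8,
                            noise_sd = 1, subject_sd = 0.5, seed = seed),
    cytof_small = sim_config(n_features = 25, n_subjects_per_batch = 250,
                             replicates_per_subject = 1, class_effect = 1.2,
                             signal_fraction = 0.4, batch_shift = 1.2,
                             batch_scale = 0.3, nonlinear_warp = 0.8,
                             noise_sd = 1, subject_sd = 0.5, seed = seed),
    planted = sim_config(n_features = 100, n_subjects_per_batch = 100,
                         replicates_per_subject = 1, class_effect = 1.5,
                         signal_fraction = 0.05, batch_shift = 1,
                         batch_scale = 0.2, nonlinear_warp = 0.5,
                         noise_sd = 1, subject_sd = 0.5, seed = seed)
  )
}
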