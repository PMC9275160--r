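# Shared fixtures: all built in code at test time.

random_table <- function(n = 5, p = 4, batch_id = "batch1", labeled = TRUE,
                         seed = 1) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * p, mean = 5), n, p),
                feature_ids = paste0("f", seq_len(p)),
                sample_ids = sprintf("s%02d", seq_len(n)),
                subject_ids = sprintf("sub%02d", ceiling(seq_len(n) / 2)),
                batch_id = batch_id,
                labels = if (labeled) rep_len(c(0L, 1L), n) else NULL)
}

# a tiny, quickly trainable two-batch problem with clear class signal
tiny_sim <- function(seed = 0, n_subjects = 60, class_effect = 2,
                     batch_shift = 1, replicates = 1) {
  generate_two_batches(sim_config(
    n_features = 10, n_subjects_per_batch = n_subjects,
    replicates_per_subject = replicates, class_effect = class_effect,
    signal_fraction = 0.5, batch_shift = batch_shift, batch_scale = 0.2,
    nonlinear_warp = 0.3, noise_sd = 1, subject_sd = 0.3, seed = seed))
}

tiny_config <- function(seed = 0, epochs = 40, minibatch_size = 64, ...) {
  train_config(weights = loss_weights(0.01, 20, 1), epochs = epochs,
               minibatch_size = minibatch_size, seed = seed, ...)
}
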