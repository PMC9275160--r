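# batchalign

Joint batch-effect removal and classification for omics feature tables
(MALDI MS metabolomics, CyTOF marker panels, and similar samples × features
intensity data).

## The problem

A classifier trained on one measurement batch (a target plate, an
acquisition day) often fails on the next batch: systematic non-biological
variation — the *batch effect* — moves the new batch away from the training
distribution. Correcting the batch effect first and classifying afterwards
helps only if the correction preserves the class signal; purely unsupervised
alignment can erase it.

`batchalign` trains three small networks **jointly** on a labeled source
batch X₁ (labels y₁) and an unlabeled target batch X₂:

* a shared **calibrator** C mapping both batches into a common latent space
  (same dimensionality as the input; batch-norm front layer, two FC + leaky
  ReLU blocks),
* per-batch **reconstructors** R₁, R₂ (three FC layers each) decoding the
  latent code back to each batch's original space, so the latent code must
  retain the sample information,
* a **discriminator** D (five FC layers, 128 → 64 → 32 → 16 → 1, sigmoid
  output) predicting the class label from the latent code, supervised by
  the source batch only.

One Adam optimizer minimizes the weighted total loss

```
L = α·L_R + β·L_C + γ·L_D
```

where `L_C` is the (multiscale Gaussian, median-heuristic) squared maximum
mean discrepancy between the two latent minibatches, `L_R` the mean squared
reconstruction residual, and `L_D` the binary cross entropy of D(C(x₁))
against y₁. Target labels are never consumed during training. The trained D
then predicts labels for the target batch; replicate samples of a subject
can be ensembled to a subject-level diagnosis by the median rule.

The package also ships the matching evaluation protocols (subsampled MMD
with an in-batch floor, ACC / F-score / AUC / MCC, label-permutation null),
a bootstrap selection-frequency biomarker screen, a fully seeded two-batch
synthetic generator, and a command-line interface.

## Worked example

```r
library(batchalign)

# Two synthetic batches: shared class signal, feature-wise shift + scale +
# monotone nonlinear warp corrupting the target batch.
sim <- generate_two_batches(presets(seed = 0)$cytof_like)

fit <- train_joint(sim$source, sim$target, train_config(seed = 0))

# How much batch effect is left in the latent space?
Zs <- calibrate(fit$model, sim$source)
Zt <- calibrate(fit$model, sim$target)
mmd_protocol(sim$source$values, sim$target$values, seed = 0)  # raw
mmd_protocol(Zs, Zt, seed = 0)                                # calibrated
in_batch_mmd(Zs, seed = 0)                                    # floor

# Does the classifier transfer?
pred <- predict(fit$model, sim$target)
classification_metrics(sim$target$labels, pred$prob)
```

Output (seed 0):

```
<mmd_estimate> 0.5541 +/- 0.0035 (n_subsample = 500, repeats = 10)
<mmd_estimate> 0.0512 +/- 0.0018 (n_subsample = 500, repeats = 10)
<mmd_estimate> 0.0488 +/- 0.0021 (n_subsample = 500, repeats = 10)
<metrics_report> [sample level, n = 1500] ACC 0.900 | F 0.901 | AUC 0.961 | MCC 0.800
```

Reading: the raw between-batch MMD (0.55) collapses to 0.051 after
calibration — statistically indistinguishable from the in-batch floor
(0.049), i.e. the latent space carries no more between-batch discrepancy
than two random halves of one batch. The source-trained discriminator then
classifies the never-labeled target batch at ACC 0.90 / AUC 0.96. For
comparison, the same architecture trained on raw source data alone
(`loss_weights(0, 0, 1)`) reaches ACC 0.687 on this target batch.

The same pipeline from the shell:

```sh
batchalign simulate --preset cytof_like --seed 0 --outdir runs/sim
batchalign train    --source runs/sim/source.csv --target runs/sim/target.csv \
                    --seed 0 --outdir runs/fit
batchalign evaluate --checkpoint runs/fit/checkpoint.json \
                    --target runs/sim/target.csv --source runs/sim/source.csv \
                    --seed 0 --outdir runs/eval
```

Every command writes a `manifest.json` (seed, config hash, input digests),
logs to stderr, and is digest-reproducible under a fixed seed.

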