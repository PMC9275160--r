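---
title: "Joint batch-effect calibration and classification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint batch-effect calibration and classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput feature tables — MALDI MS intensity spectra binned over m/z,
CyTOF marker panels — are acquired in batches (target plates, acquisition
days, instruments). Systematic non-biological differences between batches,
the *batch effect*, can dominate the biological signal, so a classifier
trained on one labeled batch (the *source*) often fails on a new unlabeled
batch (the *target*). Location-scale corrections (per-feature additive and
multiplicative adjustment) assume a form of distortion that real batch
effects routinely violate, and purely unsupervised alignment can erase the
class signal along with the batch signal.

`batchalign` trains three small networks jointly so that batch-effect
removal and classification support each other:

* a shared **calibrator** $C$ mapping both batches into a common latent
  space of the same dimensionality as the input,
* two per-batch **reconstructors** $R_1, R_2$ decoding the latent code back
  to each batch's original space, which forces the latent code to retain
  the information in the samples,
* a **discriminator** $D$ predicting the binary class label from the latent
  code, supervised by the source batch only.

With source samples $x_1^{(i)}$ (labels $y_1^{(i)}$) and target samples
$x_2^{(j)}$, the objective is the weighted sum

$$
\mathcal{L} \;=\; \alpha\,\mathcal{L}_R \;+\; \beta\,\mathcal{L}_C
\;+\; \gamma\,\mathcal{L}_D ,
$$

where $\mathcal{L}_C$ is the squared maximum mean discrepancy (MMD) between
the two latent minibatches, $\mathcal{L}_R$ the mean squared reconstruction
residual of both batches through their own reconstructors, and
$\mathcal{L}_D$ the binary cross entropy of $D(C(x_1))$ against the source
labels. Target labels are never consumed during training; they enter only
when the user evaluates predictions. A single Adam optimizer drives all
parameters; there is no alternating adversarial schedule.

## Architectures

All hidden widths equal the input dimensionality $d$ — the latent space is
deliberately *not* compressed, since compressing it measurably hurts
downstream classification on this family of data:

* calibrator: batch-norm, then FC($d{\to}d$) + leaky ReLU, twice;
* reconstructors: FC–leaky–FC–leaky–FC, all widths $d$;
* discriminator: five FC layers $d \to 128 \to 64 \to 32 \to 16 \to 1$ with
  four leaky ReLUs and a terminal sigmoid.

The leaky-rectifier negative slope defaults to 0.01 and every FC layer
shares one initialization strategy (uniform Kaiming-style fan-in scaling),
so a `(input_dim, seed)` pair reproduces a model bit-for-bit.

### The batch-norm front layer and inference statistics

The calibrator's first layer is batch normalization, which raises a design
question none of the layer equations settle: which statistics should it use
when the two batches flow through it during training? We pass the source
and target minibatches through the calibrator as a **single concatenated
forward pass**. The alternative — normalizing each batch's minibatch by its
own statistics — makes the layer itself a per-batch standardizer during
training, but inference then uses pooled running statistics that match
neither batch, so the location/scale component of the batch effect
reappears exactly where it matters (we verified this: with per-batch
minibatch statistics, the eval-mode latent MMD stays near its raw value).
With the concatenated pass, training statistics and pooled inference
statistics agree, and the downstream FC layers — not the normalizer — learn
to collapse the batch-discriminating directions, which is what the MMD loss
actually rewards.

After training we set the batch-norm running statistics exactly to the
equal-weight per-batch moments of the full training data (each batch
contributes equally, matching the 50/50 minibatch mix), instead of leaving
whatever the momentum-smoothed running average happened to end on. The
returned parameters are the average of the last 20% of epoch iterates
(Polyak-style tail averaging), a standard variance-reduction finish for
constant-ish step-size optimization.

## The MMD loss

The latent-divergence loss ships in two forms (`kernel_config()`):

* `multiscale_gaussian` (training default): the biased V-statistic estimate
  of squared MMD under a sum of Gaussian kernels. Bandwidths are the median
  heuristic of the pooled pairwise squared distances times the multipliers
  $\{0.25, 0.5, 1, 2, 4\}$, recomputed per minibatch and treated as
  constants by the gradient (the standard stop-gradient convention). The
  V-statistic is nonnegative by construction, which keeps the loss stable
  under minimization; the unbiased U-statistic is available for evaluation
  parity studies.
* `linear_mean_l1`: the L1 distance between the latent column means — the
  literal per-pair first-moment reading of a sample-wise L1 divergence.
  It is cheap and interpretable but blind to everything beyond the mean,
  so it is not the training default.

The discrimination loss is the full two-sided binary cross entropy. A
one-sided variant (positive-class term only) exists behind
`discrimination_loss(one_sided = TRUE)` for audit; it cannot train a
classifier because negative samples contribute no gradient.

## Training defaults and why

The loss weights are not dictated by the model; they balance terms of very
different scales. With intensity-scale data and $d$ features,
$\mathcal{L}_R$ is of order $d \cdot \sigma^2$ (tens to hundreds), while
the squared MMD and the BCE are order $10^{-1}$. Equal weights let the
reconstruction gradient drown the calibration gradient in the shared
calibrator, and the measured latent MMD barely moves. The defaults

| parameter | default | role |
|---|---|---|
| `alpha` | 0.01 | reconstruction weight; keeps $\alpha\mathcal{L}_R$ at order 1 |
| `beta` | 30 | calibration weight; makes alignment the dominant pressure on $C$ |
| `gamma` | 1 | discrimination weight |
| `epochs` | 300 | passes over the larger batch |
| `minibatch_size` | 256 | rows per batch per step; larger minibatches sharpen the MMD estimate |
| `learning_rate` | 2e-3 | Adam step size |
| `lr_decay` | 0.99 | per-epoch multiplicative decay; anneals to ~5% over 300 epochs |
| `weight_decay` | 1e-4 | decoupled L2 on FC weight matrices |
| `param_avg_tail` | 0.2 | fraction of final epochs averaged into the returned model |

were chosen on the synthetic suite at desk scale as the configuration from
which the calibrated latent MMD reaches the in-batch floor and training is
stable across seeds; they are echoed in every log and serializable to the
run config. Unequal batch sizes are handled by iterating each epoch over
the larger batch and resampling the smaller batch with replacement per
step, so every source sample supervises the discriminator every epoch.

The decision threshold for hard labels defaults to 0.5 with a `>=`
convention (a subject-median tie at exactly the threshold labels 1).

## Evaluation protocols

* **Subsampled MMD** (`mmd_protocol()`): mean ± SD of the kernel MMD over
  10 random draws of 500 rows per side. A side with at most 500 rows
  contributes all of its rows — resampling an already complete side would
  only inject noise. The reported value is the square root of the clipped
  squared-MMD estimate.
* **In-batch MMD** (`in_batch_mmd()`): the same computation between two
  random disjoint halves of one batch. Since no batch effect exists within
  a batch, this is the empirical floor that a perfect correction could
  reach.
* **Metrics** (`classification_metrics()`): ACC; F-score on class 1; AUC by
  the rank (Mann–Whitney) statistic, exact on small samples with ties
  counted 1/2; MCC with the zero-denominator-gives-0 convention. A
  single-class truth vector flags AUC as undefined rather than inventing a
  number.
* **Subject-level ensembling** (`ensemble_to_subject()`): replicate sample
  probabilities are reduced to their median per subject, then thresholded.
* **Permutation null** (`permutation_test()`): the source labels are
  shuffled, the entire pipeline retrained, and the target accuracy
  recorded, repeatedly; the histogram (default bin width 0.05) shows what
  accuracy is attainable without genuine label information.
* **Embedding export** (`export_embedding()`): all requested matrices are
  embedded jointly so raw and calibrated views share axes; coordinates plus
  provenance columns are the contract, plotting is the caller's. The
  available methods are PCA (default) and classical MDS — both
  deterministic; the method is pluggable by design, and t-SNE coordinates
  can be produced by any external implementation from the same matrices.

## Biomarker screen

`screen_biomarkers()` nominates features by two joint conditions: bootstrap
**selection frequency** above 0.9 — the fraction of 100 bootstrap refits of
an L1-penalized logistic regression (penalty chosen by inner
cross-validation, `lambda.1se`) in which the feature receives nonzero
weight — and a per-feature two-sample **rank-sum p-value** below 0.05. The
p-values are intentionally not multiplicity-corrected: the frequency filter
is the primary screen, and the paired raw-p cutoff mirrors the convention
this screen follows in practice. Both thresholds are strict inequalities,
and raising either can only shrink the candidate set.

## The synthetic generator

`generate_two_batches()` emulates the structure that matters for testing
this method, with all parameters explicit in `sim_config()`:

* subject-level class labels at a configurable balance; a per-subject
  random effect; 1–5 replicate samples per subject with i.i.d. noise —
  the replicate structure of repeated MS acquisition;
* a class shift of configurable magnitude on a configurable fraction of
  features, with random signs;
* a target-batch corruption
  $x \mapsto s_f\,(x + w \sin(x/2)) + t_f$ per feature $f$: additive shifts
  $t_f \sim \mathcal{N}(0, \text{batch\_shift}^2)$, log-normal scales
  $s_f = e^{\mathcal{N}(0, \text{batch\_scale}^2)}$, and a monotone
  sinusoidal warp of strength $w$. The warp is deliberately outside the
  location-scale family, so corrections that assume additive-plus-
  multiplicative distortion cannot fully remove it;
* a softplus floor keeping intensities nonnegative.

The presets fix the reference conditions: `cytof_like` (25 features, 1500
single-replicate subjects per batch, class effect 1.2 SD on 40% of
features, batch shift 1.2, scale 0.3, warp 0.8), `maldi_like` (814
features, 200 subjects × 5 replicates), `cytof_small` (a 250-subject
reduction for protocols that retrain many times), and `planted` (100
features, 5 carrying signal, for screen-recovery studies). The `cytof_like`
noise and effect levels were chosen once as a realistic
moderately-hard regime: the raw between-batch MMD sits an order of
magnitude above the in-batch floor, and a source-only classifier loses
roughly 10–20 accuracy points crossing batches.

What the generator does **not** emulate: spectral-domain structure (peak
shapes, isotope envelopes, correlated baselines), feature-feature
correlation beyond the subject random effect, label-dependent batch
composition, and more than two batches. Passing tests on this generator
demonstrates that the machinery behaves as designed under known ground
truth — not that any particular real dataset will reach the same numbers.

## Numerical choices and degenerate inputs

* Squared-MMD estimates are clipped at zero before any square root.
* The Gaussian estimator refuses single-row sides; the protocol functions
  refuse width mismatches; `train_joint()` refuses unlabeled or
  single-class sources and mismatched feature orderings.
* The median-heuristic bandwidth falls back to 1 when all pairwise
  distances are zero (constant input).
* BCE requires probabilities strictly inside (0, 1); the training path
  computes it from logits, and `discriminate()` clamps its output to
  $[10^{-12}, 1 - 10^{-12}]$.
* Stratified cross-validation errors out when a class has fewer members
  than folds rather than silently producing single-class folds.
* Checkpoints are a single JSON document carrying every parameter tensor at
  full double precision plus a shape manifest, so a saved model is
  auditable as text and reloads bit-exactly.

## Problem sizes used by the test and acceptance runs

The shipped test-suite and the acceptance script run entirely on the
synthetic generator at the preset scales above: full `cytof_like`
(1500 + 1500 samples × 25 features) for the batch-effect-removal and
transfer checks, `cytof_small` for the 20-permutation null, the `planted`
preset for screen recovery, and reduced epoch counts for protocols that
retrain the pipeline many times. These sizes are the package's reference
conditions; scaling any of them up is a matter of configuration, not code.

## Known limitations

* Single-source, single-target only; multi-batch studies must be handled
  pairwise.
* Binary classification only; multi-class inputs are rejected at
  validation.
* Marginal MMD alignment cannot guarantee class-conditional alignment: when
  a batch distortion happens to map part of one class's region onto the
  other class's region of the source, accuracy loss can persist even at
  the in-batch MMD floor.
* The transfer gain over a no-calibration baseline varies with the random
  seed of both pipelines; a source-only classifier occasionally transfers
  well by luck, so single-seed comparisons overstate certainty in either
  direction.
* The QC filter direction (`keep_above`) follows the acquisition convention
  of screening for varying signals; most QC protocols keep RSD *below* a
  ceiling — set `rsd_direction` deliberately.
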