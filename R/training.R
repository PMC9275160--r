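#' Training configuration for the joint model
#'
#' @param weights a [loss_weights()]. The defaults `alpha = 0.01`,
#'   `beta = 30`, `gamma = 1` balance the very different natural scales of
#'   the three terms (see the methods vignette): the reconstruction residual
#'   is of order `n_features * intensity^2` while the squared MMD and the
#'   BCE are of order 0.1, and equal weights would let reconstruction drown
#'   the calibration gradient in the shared calibrator.
#' @param kernel a [kernel_config()] for the calibration loss.
#' @param epochs number of passes over the larger batch (default 300).
#' @param minibatch_size rows per minibatch per batch (default 256; larger
#'   minibatches sharpen the per-step MMD estimate; at least 2 when the
#'   Gaussian kernel is active).
#' @param learning_rate Adam step size (default 2e-3).
#' @param optimizer optimizer name; only `"adam"` (first/second moment decay
#'   rates at their conventional defaults 0.9 and 0.999) is available.
#' @param lr_decay multiplicative per-epoch learning-rate factor in (0, 1]
#'   (default 0.99: the step size anneals to about 13% of its initial value
#'   over 200 epochs, which settles the latent alignment once the losses
#'   plateau).
#' @param weight_decay decoupled L2 weight decay applied to affine weight
#'   matrices only (not biases or batch-norm parameters); default 1e-4.
#' @param param_avg_tail fraction of final epochs whose parameters are
#'   averaged into the returned model (Polyak-style tail averaging; default
#'   0.2, i.e. the last 20% of epochs). `0` disables averaging and returns
#'   the last iterate.
#' @param seed integer seed controlling initialization, minibatch order and
#'   fold assignment.
#' @param decision_threshold probability cutoff for hard labels, in (0, 1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(weights = loss_weights(alpha = 0.01, beta = 30,
                                                gamma = 1),
                         kernel = kernel_config(),
                         epochs = 300L, minibatch_size = 256L,
                         learning_rate = 2e-3, optimizer = "adam",
                         lr_decay = 0.99, weight_decay = 1e-4,
                         param_avg_tail = 0.2,
                         seed = 0L, decision_threshold = 0.5) {
  stopifnot(inherits(weights, "loss_weights"), inherits(kernel, "kernel_config"))
  if (epochs < 1) abort_ba("epochs must be >= 1")
  if (minibatch_size < 1) abort_ba("minibatch_size must be >= 1")
  if (kernel$kind == "multiscale_gaussian" && minibatch_size < 2)
    abort_ba("minibatch_size must be >= 2 with the Gaussian kernel")
  if (learning_rate <= 0) abort_ba("learning_rate must be positive")
  if (!identical(optimizer, "adam")) abort_ba("unsupported optimizer '%s'", optimizer)
  if (lr_decay <= 0 || lr_decay > 1) abort_ba("lr_decay must lie in (0, 1]")
  if (weight_decay < 0) abort_ba("weight_decay must be nonnegative")
  if (param_avg_tail < 0 || param_avg_tail > 1)
    abort_ba("param_avg_tail must lie in [0, 1]")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    abort_ba("decision_threshold must lie in (0, 1)")
  structure(list(weights = weights, kernel = kernel,
                 epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 lr_decay = lr_decay, weight_decay = weight_decay,
                 param_avg_tail = param_avg_tail,
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold),
            class = "train_config")
}

sigmoid_stable <- function(u) ifelse(u >= 0, 1 / (1 + exp(-u)), exp(u) / (1 + exp(u)))

# Numerically stable mean BCE from logits: log(1 + e^u) - y * u, elementwise.
bce_from_logits <- function(u, y) {
  mean(pmax(u, 0) - y * u + log1p(exp(-abs(u))))
}

validate_pair <- function(source, target) {
  stopifnot(inherits(source, "feature_table"), inherits(target, "feature_table"))
  if (ncol(source$values) != ncol(target$values))
    abort_ba("source and target have different feature counts (%d vs %d)",
             ncol(source$values), ncol(target$values))
  if (!identical(source$feature_ids, target$feature_ids))
    abort_ba("source and target feature identifiers differ or are reordered")
  if (is.null(source$labels)) abort_ba("source batch must carry binary labels")
  if (length(unique(source$labels)) < 2L)
    abort_ba("source labels must contain both classes")
}

#' Jointly train calibrator, reconstructors and discriminator
#'
#' One optimizer drives the weighted total loss
#' `L = alpha * L_R + beta * L_C + gamma * L_D` (no alternating adversarial
#' schedule). Each step draws one minibatch per batch; the two minibatches
#' pass through the shared calibrator as a single concatenated forward pass,
#' so the batch-normalization statistics of every training step match the
#' pooled running statistics later used at inference. The calibration loss
#' compares the two latent minibatches, the reconstruction loss sends each
#' latent minibatch through its own reconstructor, and the discrimination
#' loss is computed on the source minibatch only — target labels are never
#' consumed (a labeled target table trains byte-identically to an unlabeled
#' one).
#'
#' With `alpha = beta = 0` the target batch is not consumed at all and
#' training degenerates to a plain supervised classifier `D(C(.))` on the
#' source batch (the calibration term is then reported as zero in the
#' trace).
#'
#' Each epoch iterates minibatches over the larger participating batch; the
#' smaller batch is resampled with replacement so that every source sample
#' supervises the discriminator every epoch. Runs are bit-for-bit
#' reproducible under a fixed seed.
#'
#' Two standard finishing steps are applied: the returned parameters are the
#' average of the final-epoch iterates (see `param_avg_tail` in
#' [train_config()]), and the calibrator's batch-normalization statistics
#' are then set exactly to the equal-weight per-batch moments of the full
#' training data, so inference-mode normalization matches the 50/50
#' minibatch mix seen during training.
#'
#' @param source labeled [feature_table()] (binary labels required).
#' @param target [feature_table()] sharing the source's features; labels, if
#'   present, are ignored.
#' @param cfg a [train_config()].
#' @return A list with `model` (the trained `model_state`) and `report`
#'   (class `train_report`: per-epoch loss trace data frame, elapsed
#'   seconds, and the configuration echo).
#' @export
train_joint <- function(source, target, cfg = train_config()) {
  validate_pair(source, target)
  stopifnot(inherits(cfg, "train_config"))
  t0 <- proc.time()[["elapsed"]]
  p <- ncol(source$values)
  w <- cfg$weights
  use_target <- w$alpha > 0 || w$beta > 0
  X1 <- source$values
  y1 <- as.numeric(source$labels)
  X2 <- target$values
  n1 <- nrow(X1); n2 <- nrow(X2)
  mb <- cfg$minibatch_size

  model <- init_model(p, seed = derive_seed(cfg$seed, 1L),
                      negative_slope = 0.01)
  stacks <- list(cal = model$calibrator, r1 = model$reconstructors[[1]],
                 r2 = model$reconstructors[[2]], dsc = model$discriminator)
  # drop the terminal sigmoid during training: the BCE is computed from
  # logits for numerical stability
  dsc_logit <- stacks$dsc[-length(stacks$dsc)]
  opt <- adam_state(list(stacks$cal, stacks$r1, stacks$r2, dsc_logit))
  trace <- matrix(NA_real_, cfg$epochs, 4,
                  dimnames = list(NULL, c("l_r", "l_c", "l_d", "total")))
  step_t <- 0L

  lr_decay <- cfg$lr_decay %||% 1
  weight_decay <- cfg$weight_decay %||% 0
  avg_tail <- cfg$param_avg_tail %||% 0
  avg_from <- if (avg_tail > 0) cfg$epochs - floor(avg_tail * cfg$epochs) + 1L
              else cfg$epochs + 1L
  avg_acc <- NULL
  n_avg <- 0L
  with_seed(derive_seed(cfg$seed, 2L), {
    n_drive <- if (use_target) max(n1, n2) else n1
    lr_epoch <- cfg$learning_rate
    for (epoch in seq_len(cfg$epochs)) {
      perm1 <- sample.int(n1)
      perm2 <- if (use_target) sample.int(n2) else integer(0)
      n_steps <- max(1L, floor(n_drive / mb))
      ep_loss <- c(l_r = 0, l_c = 0, l_d = 0, total = 0)
      for (s in seq_len(n_steps)) {
        take <- min(mb, n_drive)
        # driver batch: contiguous slice of its permutation; other batch:
        # resampled with replacement to the same minibatch size
        lo <- (s - 1L) * take
        pick <- function(n, perm) {
          if (n >= lo + take) perm[(lo + 1L):(lo + take)]
          else sample.int(n, take, replace = TRUE)
        }
        i1 <- pick(n1, perm1)
        Xb1 <- X1[i1, , drop = FALSE]
        yb1 <- y1[i1]
        if (use_target) {
          i2 <- pick(n2, perm2)
          Xb2 <- X2[i2, , drop = FALSE]
          Xin <- rbind(Xb1, Xb2)
        } else {
          Xin <- Xb1
        }
        fc <- stack_forward(stacks$cal, Xin, training = TRUE)
        stacks$cal <- fc$stack
        nb1 <- nrow(Xb1)
        Z1 <- fc$out[seq_len(nb1), , drop = FALSE]
        Z2 <- if (use_target) fc$out[-seq_len(nb1), , drop = FALSE] else NULL

        # reconstruction (trace always when the target participates)
        l_r <- 0; dZ1 <- Z1 * 0; dZ2 <- if (use_target) Z2 * 0 else NULL
        g_r1 <- NULL; g_r2 <- NULL
        if (use_target) {
          fr1 <- stack_forward(stacks$r1, Z1, training = TRUE)
          fr2 <- stack_forward(stacks$r2, Z2, training = TRUE)
          l_r <- reconstruction_loss(Xb1, fr1$out) +
            reconstruction_loss(Xb2, fr2$out)
          if (w$alpha > 0) {
            b1 <- stack_backward(stacks$r1, fr1$caches,
                                 w$alpha * 2 * (fr1$out - Xb1) / nb1)
            b2 <- stack_backward(stacks$r2, fr2$caches,
                                 w$alpha * 2 * (fr2$out - Xb2) / nrow(Xb2))
            dZ1 <- dZ1 + b1$dX
            dZ2 <- dZ2 + b2$dX
            g_r1 <- b1$grads; g_r2 <- b2$grads
          }
        }

        # calibration (MMD) between the two latent minibatches
        l_c <- 0
        if (use_target) {
          cg <- calibration_loss_grad(Z1, Z2, cfg$kernel,
                                      want_grad = w$beta > 0)
          l_c <- cg$loss
          if (w$beta > 0) {
            dZ1 <- dZ1 + w$beta * cg$dZ1
            dZ2 <- dZ2 + w$beta * cg$dZ2
          }
        }

        # discrimination on the source minibatch only
        fd <- stack_forward(dsc_logit, Z1, training = TRUE)
        u <- as.numeric(fd$out)
        l_d <- bce_from_logits(u, yb1)
        g_d <- NULL
        if (w$gamma > 0) {
          du <- matrix(w$gamma * (sigmoid_stable(u) - yb1) / nb1, ncol = 1L)
          bd <- stack_backward(dsc_logit, fd$caches, du)
          dZ1 <- dZ1 + bd$dX
          g_d <- bd$grads
        }

        dZ <- if (use_target) rbind(dZ1, dZ2) else dZ1
        bc <- stack_backward(stacks$cal, fc$caches, dZ)
        step_t <- step_t + 1L
        # NULL gradient lists mark gradient-inert stacks (weight zero): Adam
        # skips them entirely, so neither moments nor weight decay touch them
        upd <- adam_step(
          list(stacks$cal, stacks$r1, stacks$r2, dsc_logit),
          list(bc$grads, g_r1, g_r2, g_d),
          opt, lr = lr_epoch, t = step_t, weight_decay = weight_decay)
        stacks$cal <- upd$stacks[[1]]
        stacks$r1 <- upd$stacks[[2]]
        stacks$r2 <- upd$stacks[[3]]
        dsc_logit <- upd$stacks[[4]]
        opt <- upd$opt

        tot <- total_loss(l_r, l_c, l_d, w)
        ep_loss <- ep_loss + c(l_r, l_c, l_d, tot)
      }
      trace[epoch, ] <- ep_loss / n_steps
      if (any(!is.finite(trace[epoch, ])))
        abort_ba("non-finite loss at epoch %d; lower the learning rate", epoch)
      lr_epoch <- lr_epoch * lr_decay
      if (epoch >= avg_from) {
        snap <- list(stacks$cal, stacks$r1, stacks$r2, dsc_logit)
        avg_acc <- if (is.null(avg_acc)) snap
                   else mapply(stack_add, avg_acc, snap, SIMPLIFY = FALSE)
        n_avg <- n_avg + 1L
      }
    }
  })

  if (n_avg > 0L) {
    avg <- lapply(avg_acc, stack_scale, s = 1 / n_avg)
    stacks$cal <- avg[[1]]; stacks$r1 <- avg[[2]]; stacks$r2 <- avg[[3]]
    dsc_logit <- avg[[4]]
  }
  # finalize the calibrator's batch-norm statistics exactly: equal-weight
  # per-batch moments over the full data, matching the 50/50 minibatch mix
  # seen during training (source-only when the target is not consumed)
  bn <- stacks$cal[[1]]
  if (identical(bn$kind, "batch_norm")) {
    moments <- function(X) {
      mu <- colMeans(X)
      list(mu = mu, ex2 = colMeans(X * X))
    }
    m1 <- moments(X1)
    if (use_target) {
      m2 <- moments(X2)
      mu <- (m1$mu + m2$mu) / 2
      ex2 <- (m1$ex2 + m2$ex2) / 2
    } else {
      mu <- m1$mu; ex2 <- m1$ex2
    }
    bn$running_mean <- mu
    bn$running_var <- pmax(ex2 - mu * mu, 0)
    stacks$cal[[1]] <- bn
  }

  model$calibrator <- stacks$cal
  model$reconstructors <- list(stacks$r1, stacks$r2)
  model$discriminator <- c(dsc_logit, list(nn_sigmoid(1L)))
  report <- structure(
    list(trace = as.data.frame(trace), epochs = cfg$epochs,
         seconds = proc.time()[["elapsed"]] - t0, config = cfg),
    class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<train_report> %d epochs in %.1fs | final: L_R %.4g, L_C %.4g, L_D %.4g, total %.4g\n",
              x$epochs, x$seconds, last$l_r, last$l_c, last$l_d, last$total))
  cat(sprintf("  config: alpha=%g beta=%g gamma=%g, kernel=%s, mb=%d, lr=%g, seed=%d\n",
              x$config$weights$alpha, x$config$weights$beta,
              x$config$weights$gamma, x$config$kernel$kind,
              x$config$minibatch_size, x$config$learning_rate, x$config$seed))
  invisible(x)
}

#' Predict class probabilities and labels for new samples
#'
#' Runs `D(C(X))` in evaluation mode.
#'
#' @param object a trained `model_state`.
#' @param newdata numeric matrix or [feature_table()] with matching feature
#'   width.
#' @param threshold probability cutoff; a sample is labeled 1 iff its
#'   probability is `>= threshold`.
#' @param ... unused.
#' @return A list with `prob` (numeric vector) and `label` (integer 0/1
#'   vector), both aligned to the rows of `newdata`.
#' @export
predict.model_state <- function(object, newdata, threshold = 0.5, ...) {
  p <- discriminate(object, calibrate(object, newdata))
  list(prob = p, label = as.integer(p >= threshold))
}

#' Stratified in-batch cross-validation
#'
#' Splits one labeled batch into stratified folds under the configuration
#' seed; for each fold the remaining folds train the joint model while the
#' held-out fold plays the unlabeled-target role for the calibration loss,
#' and the held-out samples are then scored. Metrics are computed once on
#' the pooled held-out predictions (not averaged per fold).
#'
#' @param batch labeled [feature_table()] containing both classes.
#' @param folds number of folds (default 10).
#' @param cfg a [train_config()].
#' @return A `metrics_report` (see [classification_metrics()]) at the sample
#'   level, with the pooled per-sample predictions attached as attribute
#'   `"predictions"`.
#' @export
in_batch_cross_validation <- function(batch, folds = 10L, cfg = train_config()) {
  stopifnot(inherits(batch, "feature_table"))
  if (is.null(batch$labels)) abort_ba("cross-validation requires labels")
  folds <- as.integer(folds)
  if (folds < 2L) abort_ba("folds must be >= 2")
  y <- batch$labels
  if (min(table(y)) < folds)
    abort_ba("stratification error: a class has fewer samples (%d) than folds (%d)",
             min(table(y)), folds)
  n <- length(y)
  assign_folds <- with_seed(derive_seed(cfg$seed, 3L), {
    f <- integer(n)
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  prob <- numeric(n)
  for (k in seq_len(folds)) {
    hold <- assign_folds == k
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(cfg$seed, 100L + k)
    fit <- train_joint(subset_samples(batch, !hold),
                       subset_samples(batch, hold), cfg_k)
    prob[hold] <- predict(fit$model, subset_samples(batch, hold))$prob
  }
  rep_out <- classification_metrics(y, prob, threshold = cfg$decision_threshold)
  attr(rep_out, "predictions") <- data.frame(
    sample = batch$sample_ids, fold = assign_folds, label = y, prob = prob,
    stringsAsFactors = FALSE)
  rep_out
}
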