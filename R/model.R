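#' Initialize the calibrator/reconstructor/discriminator model
#'
#' Builds the three network families operating on `input_dim`-dimensional
#' feature vectors:
#'
#' * **Calibrator `C`** — batch normalization, then two fully connected (FC)
#'   layers each followed by a leaky rectifier. Every hidden width equals
#'   `input_dim`, so the latent code is never compressed.
#' * **Reconstructors `R1`, `R2`** — one decoder per batch: three FC layers
#'   with two interleaved leaky rectifiers, all widths `input_dim`, mapping
#'   the latent code back to the input space.
#' * **Discriminator `D`** — five FC layers narrowing from `input_dim` to
#'   128, 64, 32, 16 and finally 1, with four interleaved leaky rectifiers
#'   and a terminal sigmoid producing a class probability.
#'
#' All FC layers share one initialization strategy (uniform Kaiming-style
#' fan-in scaling). Identical `(input_dim, seed, init_scheme)` produce
#' bitwise-identical parameters.
#'
#' @param input_dim number of features (>= 1).
#' @param seed integer RNG seed for parameter initialization.
#' @param init_scheme initialization strategy name; `"kaiming_uniform"`.
#' @param negative_slope leaky-rectifier slope for negative inputs
#'   (default 0.01).
#' @param bn_momentum,bn_eps batch-normalization running-statistics momentum
#'   and variance floor (defaults 0.1 and 1e-5).
#' @return An object of class `model_state`.
#' @export
init_model <- function(input_dim, seed = 0L, init_scheme = "kaiming_uniform",
                       negative_slope = 0.01, bn_momentum = 0.1,
                       bn_eps = 1e-5) {
  if (!is.numeric(input_dim) || length(input_dim) != 1L || input_dim < 1)
    abort_ba("input_dim must be a positive integer")
  input_dim <- as.integer(input_dim)
  with_seed(seed, {
    calibrator <- list(
      nn_batch_norm(input_dim, momentum = bn_momentum, eps = bn_eps),
      nn_affine(input_dim, input_dim, init_scheme),
      nn_leaky(input_dim, negative_slope),
      nn_affine(input_dim, input_dim, init_scheme),
      nn_leaky(input_dim, negative_slope))
    make_recon <- function() list(
      nn_affine(input_dim, input_dim, init_scheme),
      nn_leaky(input_dim, negative_slope),
      nn_affine(input_dim, input_dim, init_scheme),
      nn_leaky(input_dim, negative_slope),
      nn_affine(input_dim, input_dim, init_scheme))
    r1 <- make_recon()
    r2 <- make_recon()
    widths <- c(input_dim, 128L, 64L, 32L, 16L, 1L)
    discriminator <- list()
    for (i in 1:5) {
      discriminator[[length(discriminator) + 1L]] <-
        nn_affine(widths[i], widths[i + 1L], init_scheme)
      if (i < 5L)
        discriminator[[length(discriminator) + 1L]] <-
          nn_leaky(widths[i + 1L], negative_slope)
    }
    discriminator[[length(discriminator) + 1L]] <- nn_sigmoid(1L)
    structure(
      list(input_dim = input_dim, seed = as.integer(seed),
           init_scheme = init_scheme, negative_slope = negative_slope,
           calibrator = calibrator,
           reconstructors = list(r1, r2),
           discriminator = discriminator),
      class = "model_state")
  })
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> input_dim = %d, seed = %d\n", x$input_dim, x$seed))
  cat("  calibrator:    ", paste(vapply(x$calibrator, `[[`, "", "kind"), collapse = " -> "), "\n")
  cat("  reconstructors:", length(x$reconstructors), "stacks of",
      paste(vapply(x$reconstructors[[1]], `[[`, "", "kind"), collapse = " -> "), "\n")
  cat("  discriminator: ", paste(vapply(x$discriminator, `[[`, "", "kind"), collapse = " -> "), "\n")
  invisible(x)
}

#' Describe the layer sequences of a model
#'
#' @param model a [init_model()] state.
#' @return A data frame with one row per layer (stack, position, kind,
#'   input and output widths), suitable for structural checks.
#' @export
model_architecture <- function(model) {
  stopifnot(inherits(model, "model_state"))
  stacks <- c(list(calibrator = model$calibrator),
              stats::setNames(model$reconstructors,
                              c("reconstructor1", "reconstructor2")),
              list(discriminator = model$discriminator))
  do.call(rbind, lapply(names(stacks), function(nm) {
    st <- stacks[[nm]]
    data.frame(stack = nm, position = seq_along(st),
               kind = vapply(st, `[[`, "", "kind"),
               in_width = vapply(st, function(l) as.integer(l$n_in), 1L),
               out_width = vapply(st, function(l) as.integer(l$n_out), 1L),
               stringsAsFactors = FALSE)
  }))
}

as_value_matrix <- function(X, input_dim, what = "X") {
  if (inherits(X, "feature_table")) X <- X$values
  X <- check_matrix(X, what)
  if (ncol(X) != input_dim)
    abort_ba("`%s` has %d columns but the model expects %d features",
             what, ncol(X), input_dim)
  X
}

#' Map samples into the calibrated latent space
#'
#' Applies the calibrator `C` in evaluation mode: `Z = C(X)`. The
#' batch-normalization layer uses its accumulated running statistics (the
#' statistics gathered from both batches' minibatches during joint training);
#' minibatch statistics are used only inside [train_joint()].
#'
#' @param model a `model_state`.
#' @param X numeric matrix (or [feature_table()]) with `input_dim` columns.
#' @return Latent matrix `Z` with the same shape as `X` (the latent space is
#'   never compressed).
#' @export
calibrate <- function(model, X) {
  stopifnot(inherits(model, "model_state"))
  X <- as_value_matrix(X, model$input_dim)
  stack_forward(model$calibrator, X, training = FALSE)$out
}

#' Reconstruct samples from latent codes
#'
#' Each batch owns its reconstructor: `R1` decodes batch-1 latents, `R2`
#' batch-2 latents, so batch-specific rendering is reinstated outside the
#' shared latent space.
#'
#' @param model a `model_state`.
#' @param Z latent matrix with `input_dim` columns.
#' @param which_batch 1 or 2, selecting `R1` or `R2`.
#' @return Reconstructed matrix of the same shape as `Z`.
#' @export
reconstruct <- function(model, Z, which_batch) {
  stopifnot(inherits(model, "model_state"))
  if (!which_batch %in% c(1L, 2L))
    abort_ba("which_batch must be 1 or 2, got %s", toString(which_batch))
  Z <- as_value_matrix(Z, model$input_dim, "Z")
  stack_forward(model$reconstructors[[which_batch]], Z, training = FALSE)$out
}

#' Score latent codes with the discriminator
#'
#' @param model a `model_state`.
#' @param Z latent matrix with `input_dim` columns.
#' @return Numeric vector of class-1 probabilities, one per row, strictly
#'   inside (0, 1).
#' @export
discriminate <- function(model, Z) {
  stopifnot(inherits(model, "model_state"))
  Z <- as_value_matrix(Z, model$input_dim, "Z")
  p <- stack_forward(model$discriminator, Z, training = FALSE)$out
  pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12)
}

# ---- Checkpoints ------------------------------------------------------------

serialize_stack <- function(stack) {
  lapply(stack, function(l) {
    out <- l[c("kind", "n_in", "n_out")]
    for (p in c("W", "b", "gamma", "beta", "running_mean", "running_var",
                "negative_slope", "momentum", "eps"))
      if (!is.null(l[[p]])) out[[p]] <- l[[p]]
    out
  })
}

deserialize_stack <- function(spec) {
  lapply(spec, function(l) {
    l$n_in <- as.integer(l$n_in)
    l$n_out <- as.integer(l$n_out)
    if (!is.null(l$W))  # jsonlite stores matrices as arrays of rows
      l$W <- matrix(unlist(l$W), l$n_in, l$n_out, byrow = TRUE)
    for (p in c("b", "gamma", "beta", "running_mean", "running_var"))
      if (!is.null(l[[p]])) l[[p]] <- as.numeric(unlist(l[[p]]))
    l
  })
}

#' Save a model checkpoint as JSON
#'
#' The checkpoint is a single self-describing JSON document: a manifest
#' (input dimension, seed, layer kinds and shapes) plus every parameter
#' tensor at full double precision, so states are auditable as plain text
#' without any training framework.
#'
#' @param model a `model_state`.
#' @param path output path (conventionally `.json`).
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "model_state"))
  doc <- list(
    format = "batchalign-checkpoint",
    version = 1L,
    manifest = list(
      input_dim = model$input_dim, seed = model$seed,
      init_scheme = model$init_scheme,
      negative_slope = model$negative_slope,
      shapes = model_architecture(model)),
    calibrator = serialize_stack(model$calibrator),
    reconstructors = lapply(model$reconstructors, serialize_stack),
    discriminator = serialize_stack(model$discriminator))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path path to a checkpoint JSON file.
#' @return A `model_state`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort_ba("checkpoint not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "batchalign-checkpoint"))
    abort_ba("%s is not a batchalign checkpoint", path)
  structure(
    list(input_dim = as.integer(doc$manifest$input_dim),
         seed = as.integer(doc$manifest$seed),
         init_scheme = doc$manifest$init_scheme,
         negative_slope = as.numeric(doc$manifest$negative_slope),
         calibrator = deserialize_stack(doc$calibrator),
         reconstructors = lapply(doc$reconstructors, deserialize_stack),
         discriminator = deserialize_stack(doc$discriminator)),
    class = "model_state")
}
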