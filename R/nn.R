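# Minimal dense-network machinery: affine, leaky-rectifier, batch-norm and
# sigmoid layers with hand-derived backward passes, plus Adam. All tensors are
# plain double matrices (rows = samples), so the whole model is inspectable
# and serializable as text. Layer caches produced by the forward pass are
# consumed by the matching backward pass.

nn_affine <- function(n_in, n_out, init_scheme = "kaiming_uniform") {
  # Kaiming-style fan-in scaling; the same scheme is shared by every affine
  # layer of every stack.
  bound <- switch(init_scheme,
    kaiming_uniform = sqrt(6 / n_in),
    abort_ba("unknown init_scheme '%s'", init_scheme))
  W <- matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out)
  b <- numeric(n_out)
  list(kind = "affine", n_in = n_in, n_out = n_out, W = W, b = b)
}

nn_leaky <- function(width, negative_slope = 0.01) {
  stopifnot(negative_slope > 0, negative_slope < 1)
  list(kind = "leaky_rectifier", n_in = width, n_out = width,
       negative_slope = negative_slope)
}

nn_batch_norm <- function(width, momentum = 0.1, eps = 1e-5) {
  list(kind = "batch_norm", n_in = width, n_out = width,
       gamma = rep(1, width), beta = numeric(width),
       running_mean = numeric(width), running_var = rep(1, width),
       momentum = momentum, eps = eps)
}

nn_sigmoid <- function(width) {
  list(kind = "sigmoid", n_in = width, n_out = width)
}

# Forward one layer. `training` switches batch-norm between minibatch
# statistics (running stats are then updated in place via the returned layer)
# and accumulated running statistics. Returns list(out, cache, layer).
layer_forward <- function(layer, X, training = FALSE) {
  switch(layer$kind,
    affine = {
      out <- X %*% layer$W
      out <- sweep(out, 2L, layer$b, "+")
      list(out = out, cache = list(X = X), layer = layer)
    },
    leaky_rectifier = {
      neg <- X < 0
      out <- X
      out[neg] <- layer$negative_slope * X[neg]
      list(out = out, cache = list(neg = neg), layer = layer)
    },
    batch_norm = {
      if (training) {
        n <- nrow(X)
        mu <- colMeans(X)
        xc <- sweep(X, 2L, mu, "-")
        v <- colMeans(xc * xc)  # biased minibatch variance
        inv_sd <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2L, inv_sd, "*")
        m <- layer$momentum
        layer$running_mean <- (1 - m) * layer$running_mean + m * mu
        # running variance stored unbiased, as is conventional
        vu <- if (n > 1L) v * n / (n - 1L) else v
        layer$running_var <- (1 - m) * layer$running_var + m * vu
        out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
        list(out = out,
             cache = list(xhat = xhat, inv_sd = inv_sd, training = TRUE),
             layer = layer)
      } else {
        inv_sd <- 1 / sqrt(layer$running_var + layer$eps)
        xhat <- sweep(sweep(X, 2L, layer$running_mean, "-"), 2L, inv_sd, "*")
        out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
        list(out = out,
             cache = list(xhat = xhat, inv_sd = inv_sd, training = FALSE),
             layer = layer)
      }
    },
    sigmoid = {
      out <- 1 / (1 + exp(-X))
      list(out = out, cache = list(out = out), layer = layer)
    },
    abort_ba("unknown layer kind '%s'", layer$kind))
}

# Backward one layer: returns list(dX, grads) where grads mirrors the layer's
# trainable parameters (NULL for parameter-free layers).
layer_backward <- function(layer, cache, dY) {
  switch(layer$kind,
    affine = {
      list(dX = dY %*% t(layer$W),
           grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
    },
    leaky_rectifier = {
      dX <- dY
      dX[cache$neg] <- layer$negative_slope * dY[cache$neg]
      list(dX = dX, grads = NULL)
    },
    batch_norm = {
      xhat <- cache$xhat
      dgamma <- colSums(dY * xhat)
      dbeta <- colSums(dY)
      if (isTRUE(cache$training)) {
        n <- nrow(dY)
        dxhat <- sweep(dY, 2L, layer$gamma, "*")
        # standard batch-norm backward through minibatch statistics
        term <- sweep(dxhat, 2L, colMeans(dxhat), "-") -
          xhat * rep(colMeans(dxhat * xhat), each = n)
        dX <- sweep(term, 2L, cache$inv_sd, "*")
      } else {
        dX <- sweep(sweep(dY, 2L, layer$gamma, "*"), 2L, cache$inv_sd, "*")
      }
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    sigmoid = {
      s <- cache$out
      list(dX = dY * s * (1 - s), grads = NULL)
    })
}

# Forward a stack (list of layers); returns final output, per-layer caches and
# the possibly updated stack (batch-norm running stats).
stack_forward <- function(stack, X, training = FALSE) {
  caches <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    step <- layer_forward(stack[[i]], X, training = training)
    X <- step$out
    caches[[i]] <- step$cache
    stack[[i]] <- step$layer
  }
  list(out = X, caches = caches, stack = stack)
}

# Backward a stack; returns input gradient and per-layer gradient list.
stack_backward <- function(stack, caches, dY) {
  grads <- vector("list", length(stack))
  for (i in rev(seq_along(stack))) {
    step <- layer_backward(stack[[i]], caches[[i]], dY)
    dY <- step$dX
    grads[i] <- list(step$grads)  # keep NULL slots (parameter-free layers)
  }
  list(dX = dY, grads = grads)
}

# ---- Adam -------------------------------------------------------------------

# Parameter access helpers: every trainable parameter of a stack is addressed
# as (layer index, parameter name).
stack_param_names <- function(stack) {
  out <- list()
  for (i in seq_along(stack)) {
    l <- stack[[i]]
    nm <- switch(l$kind, affine = c("W", "b"), batch_norm = c("gamma", "beta"),
                 character(0))
    for (p in nm) out[[length(out) + 1L]] <- list(layer = i, param = p)
  }
  out
}

adam_state <- function(stacks) {
  lapply(stacks, function(stack) {
    lapply(stack_param_names(stack), function(addr) {
      val <- stack[[addr$layer]][[addr$param]]
      list(addr = addr, m = val * 0, v = val * 0)
    })
  })
}

# One Adam step (default moment decay rates 0.9 / 0.999) over every stack in
# `stacks`, using gradient lists shaped like those from stack_backward().
# `weight_decay` is decoupled (AdamW-style) and applied to affine weight
# matrices only.
adam_step <- function(stacks, grad_lists, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (s in seq_along(stacks)) {
    slots <- opt[[s]]
    for (k in seq_along(slots)) {
      addr <- slots[[k]]$addr
      g <- grad_lists[[s]][[addr$layer]][[addr$param]]
      if (is.null(g)) next
      m <- beta1 * slots[[k]]$m + (1 - beta1) * g
      v <- beta2 * slots[[k]]$v + (1 - beta2) * g * g
      slots[[k]]$m <- m
      slots[[k]]$v <- v
      val <- stacks[[s]][[addr$layer]][[addr$param]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
      if (weight_decay > 0 && addr$param == "W")
        val <- val - lr * weight_decay * val
      stacks[[s]][[addr$layer]][[addr$param]] <- val
    }
    opt[[s]] <- slots
  }
  list(stacks = stacks, opt = opt)
}

# Elementwise sum / scaling of the numeric fields of two identically shaped
# stacks; used for Polyak tail-averaging of parameters.
stack_param_fields <- c("W", "b", "gamma", "beta", "running_mean", "running_var")

stack_add <- function(a, b) {
  for (i in seq_along(a))
    for (p in stack_param_fields)
      if (!is.null(a[[i]][[p]])) a[[i]][[p]] <- a[[i]][[p]] + b[[i]][[p]]
  a
}

stack_scale <- function(a, s) {
  for (i in seq_along(a))
    for (p in stack_param_fields)
      if (!is.null(a[[i]][[p]])) a[[i]][[p]] <- a[[i]][[p]] * s
  a
}

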