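# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a base seed and a stream index
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream) {
  # double arithmetic is exact here (products < 2^53), result < 2^31
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 40503) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message and a package condition class
#' @noRd
abort_ba <- function(...) {
  stop(structure(class = c("batchalign_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_ba("`%s` must be a numeric matrix", name)
  if (anyNA(x)) abort_ba("`%s` contains missing values", name)
  x
}
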