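# Shared internal helpers: classed errors, seed management, misc.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All package errors carry class "handsfree_error" plus a specific subclass,
# so callers and tests can distinguish failure modes without string matching.
hf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "handsfree_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `expr` under a given RNG seed and restore the caller's RNG state
# afterwards, so every generator is a pure function of (inputs, seed).
with_preserved_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a per-component sub-seed from a master seed
#'
#' A single master seed fans out deterministically to every randomised
#' component (one sub-seed per generated window, per training run, ...),
#' so one number reproduces a whole session. The derivation is an affine
#' hash modulo the largest 32-bit prime; arithmetic is done in doubles
#' (exact below 2^53) and the result always fits a 32-bit integer.
#'
#' @param master_seed integer master seed.
#' @param index nonnegative integer index of the consumer.
#' @return a single integer seed in `[1, 2147483646]`.
#' @export
#' @examples
#' derive_subseed(42, 0)
#' derive_subseed(42, 1)
derive_subseed <- function(master_seed, index) {
  stopifnot(length(master_seed) == 1, length(index) == 1, index >= 0)
  h <- (as.numeric(master_seed) %% 2147483647) * 7919 + as.numeric(index) * 104729
  as.integer(h %% 2147483646) + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_if_not_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    hf_stop(sprintf("'%s' must be TRUE or FALSE", name), "hf_validation_error")
  }
}
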