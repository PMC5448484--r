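# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this so that a
# spec (including its seed) is a complete description of the output.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream of sub-seeds (< 2^31) derived from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_unless <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
  invisible(TRUE)
}
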