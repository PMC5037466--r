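## Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(structure(class = c("chorusem_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_insufficient <- function(...) {
  stop(structure(class = c("chorusem_insufficient_data", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child RNG seed from a top-level seed
#'
#' One top-level seed fans out to per-stage child seeds by a fixed counter
#' scheme, so any pipeline stage can be rerun in isolation and still be
#' reproducible. The result is always a valid 32-bit integer seed.
#'
#' @param seed top-level integer seed.
#' @param stage stage counter (non-negative integer); distinct stages of a
#'   run use distinct counters.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (as.double(seed) %% m)
  for (k in seq_len(stage + 1)) {
    s <- (s * 48271 + 11 + 1000003 * stage) %% m
  }
  as.integer(s)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
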