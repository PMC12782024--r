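# Seed plumbing. All randomness flows from one root seed through named
# substreams so each pipeline stage is independently reproducible and the
# caller's RNG state is never disturbed.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_temp_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Derive a named substream seed from a root seed
#'
#' Deterministic 32-bit hash of the root seed and a stream label, so stages
#' (schedule, responses, ratings, volumes, permutation) draw from
#' independent, individually re-runnable streams.
#'
#' @param seed Integer root seed.
#' @param stream Character stream label.
#' @return A positive integer below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  bytes <- utf8ToInt(paste0(stream, ":", as.integer(seed)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
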