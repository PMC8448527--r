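#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from a single integer seed. Independent
#' stages (per-site simulation, rendering noise, movie noise, ...) draw their
#' own sub-seed through this documented splitting rule so that adding a stage
#' never perturbs the stream of another.
#'
#' The rule is a multiply-add hash of the master seed and a stream label,
#' reduced modulo 2^31 - 1 (R seeds are 32-bit signed integers).
#'
#' @param seed master integer seed.
#' @param stream character or integer stream label.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "render")
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  key <- if (is.character(stream)) {
    sum(as.integer(charToRaw(stream)) * seq_along(charToRaw(stream)))
  } else {
    as.integer(stream)
  }
  m <- 2147483647          # 2^31 - 1, Mersenne prime
  h <- (as.numeric(seed) %% m)
  h <- (h * 48271 + key * 16807 + 12345) %% m
  as.integer(h %% (m - 2)) + 1L
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
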