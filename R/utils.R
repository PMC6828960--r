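#' Round half away from zero
#'
#' Commercial rounding used throughout program reports (base [round()] rounds
#' half to even). `round_half_away(26776.5) == 26777`.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # tiny nudge guards against values like 42.85 stored as 42.84999...
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a user seed; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483587 + 1
}
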