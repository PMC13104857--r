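#' Derive a stream of child seeds from one root seed
#'
#' All randomised steps in the package draw their seeds from a single root
#' seed through this fixed integer recurrence, so any sub-result can be
#' reproduced in isolation. Derived seeds stay below 2^31.
#'
#' @param seed integer root seed.
#' @param k positive integer index of the child stream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  # multiplicative congruential step, modulus 2^31 - 1 (a Mersenne prime)
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) + 1
  for (i in seq_len(2)) s <- (s * 48271) %% m
  as.integer((s + as.double(k) * 2654435761) %% m)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so library calls do not disturb
#' the caller's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stderr logging used across the package; warnings always surface,
# info-level notes go through message() so they are suppressible.
ms_log <- function(...) message("[morphoscore] ", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
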