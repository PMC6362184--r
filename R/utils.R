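#' @keywords internal
"_PACKAGE"

# -- internal helpers ---------------------------------------------------------

#' Derive a child RNG seed from a base seed and a stream index
#'
#' Deterministic, order-independent derivation so that every frame / sample
#' draws from its own reproducible stream. Kept below 2^31 so the result is a
#' valid integer seed on all platforms.
#'
#' @param seed base integer seed.
#' @param k stream index (frame number, sample number, ...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k) * 1299709 + 1
  as.integer(s %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

# x * log(x) with the 0 * log(0) = 0 convention, in the given log base.
xlogx <- function(x, base = 2) ifelse(x > 0, x * log(x, base = base), 0)
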