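## Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## 32-bit FNV-1a over the raw bytes of a string; returned as a double in
## [0, 2^32) so callers can fold it into seeds or pseudo-random ranks without
## integer overflow.
#' @noRd
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  h
}

## Derive a per-component seed below 2^31 from a single global seed and a
## stream label, so independent generators never share an RNG stream.
#' @noRd
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  as.integer((abs(seed) * 69069 + fnv1a32(stream)) %% 2147483647)
}

## Run `expr` under a locally-set RNG seed, restoring the caller's RNG state.
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Nearest-integer with half-to-even tie handling (the behavior of base
## round(), asserted here so threshold arithmetic is explicit about ties).
#' @noRd
roundHalfEven <- function(x) round(x)

#' @noRd
isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < tol
}

#' @noRd
assertProb <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", what), call. = FALSE)
  invisible(x)
}
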