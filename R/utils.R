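# Internal helpers: classed errors and seed substreams.

abort_upcallr <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "upcallr_error"), ...)
}

#' Derive a named child seed from a base seed
#'
#' All pipeline stages draw their randomness from one global seed through
#' named substreams, so that each stage is independently reproducible.
#' The derived seed is a deterministic 31-bit hash of the base seed and the
#' stream name.
#'
#' @param seed Integer base seed.
#' @param name Character name of the substream (e.g. `"negatives"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- seed %% 2147483647
  for (b in utf8ToInt(name)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Run expr with the RNG seeded, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
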