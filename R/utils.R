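# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic, collision-poor mapping of (master seed, index) to a
#' 31-bit integer usable with set.seed(). Uses a small multiplicative hash
#' in double precision (exact below 2^53).
#'
#' @param master integer master seed
#' @param index non-negative integer stream index
#' @return integer seed in [0, 2^31 - 2]
#' @keywords internal
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m + 1) * 48271 %% m
  for (i in seq_len(index + 1L)) {
    x <- (x * 48271) %% m
  }
  as.integer(x %% (m - 1))
}

#' Evaluate with a local RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
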