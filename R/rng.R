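#' Derive a reproducible child seed from a master seed
#'
#' Spawns per-subject / per-fold random streams by mixing a master seed with
#' one or more integer indices through a Lehmer-style multiplicative hash.
#' The result is always in `[1, 2^31 - 2]` so it is a valid `set.seed()`
#' argument, and distinct index tuples map to distinct streams with
#' overwhelming probability.
#'
#' @param seed master integer seed.
#' @param ... integer indices (subject index, fold index, repeat index, ...).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 5)
#' derive_seed(1, 5, 2)
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed) %% m
  idx <- c(...)
  if (length(idx) == 0L) idx <- 0
  for (x in as.double(idx)) {
    # 48271: Park-Miller multiplier; products stay < 2^47, exact in doubles
    s <- (s * 48271 + (x %% m) + 1) %% m
    s <- (s * 48271 + 11) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}
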