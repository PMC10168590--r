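# Internal helpers: seeded evaluation without disturbing the caller's RNG
# state, and deterministic child-seed derivation for multi-trial protocols.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive reproducible child seeds from a master seed
#'
#' Multi-trial protocols use one master seed per experiment and derive one
#' child seed per trial deterministically, so that any individual trial can be
#' reproduced in isolation. Child seeds are integers in `[1, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  with_seed(seed, sample.int(2147483645L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
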