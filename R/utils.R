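#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R random-number generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so seeded simulations do not disturb the
#' surrounding session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @export
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

# Complex white noise with independent N(0, sd) real and imaginary parts.
complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, 0, sd), imaginary = stats::rnorm(n, 0, sd))
}

# Derive a stream of sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
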