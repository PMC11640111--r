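#' @importFrom methods new validObject is slot
#' @importFrom stats approx rnorm runif sd fft median quantile setNames dist
#' @importFrom utils head read.csv tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library code never clobbers user RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative number", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-unit seed derived from a master seed. Multiplicative
# counter hash; all arithmetic stays exact in doubles (< 2^53).
deriveSeed <- function(masterSeed, index) {
  ((masterSeed %% 2147483647) * 69069 + index * 1234567) %% 2147483647
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' @keywords internal
"_PACKAGE"
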