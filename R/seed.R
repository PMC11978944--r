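#' Derive a reproducible sub-stream seed
#'
#' All stochastic generators in the package draw from named sub-streams of a
#' single master seed, so that re-running any stage of a pipeline with the
#' same configuration reproduces its output bit-for-bit while different
#' stages remain statistically independent.
#'
#' @param seed master integer seed.
#' @param name character tag naming the sub-stream (e.g. `"phantom"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, name = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  # small multiplicative hash over the tag bytes; modulus keeps it a valid
  # 32-bit R integer
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
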