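#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed. Independent
#' consumers (phantom geometry, parameter init, batch sampling, ...) derive
#' their own stream so that adding a consumer does not perturb the others.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 2147483647
  s <- (abs(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483645 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded by (seed, stream),
# restoring the caller's state afterwards.
with_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(derive_seed(seed, stream))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
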