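#' Transformer-style sinusoidal embedding of a scalar covariate
#'
#' Maps a scalar covariate (an age in years, a BMI in kg/m2, a phase index,
#' or a gap between two such values) to a `d`-dimensional vector
#' `e[2i] = sin(value / C^(2i/d))`, `e[2i+1] = cos(value / C^(2i/d))` for
#' `i = 0 .. d/2 - 1`. The covariate is fed in natural units; the multi-scale
#' sinusoidal basis absorbs the scale, and the embedding is injective on any
#' working covariate range for `d >= 8`.
#'
#' @param value finite scalar covariate, or a vector of covariates (one
#'   embedding per element, returned as a `d x length(value)` matrix).
#' @param d even embedding length (default 64).
#' @param scale_constant the geometric frequency constant `C` (default 10000).
#' @return numeric vector of length `d` (or matrix `d x n`), components in
#'   `[-1, 1]`.
#' @export
sinusoidal_embed <- function(value, d = 64L, scale_constant = 10000) {
  if (d %% 2 != 0 || d < 2) stop("embedding length d must be even and >= 2")
  if (!all(is.finite(value))) stop("covariate value must be finite")
  i <- 0:(d / 2 - 1)
  freq <- 1 / scale_constant^(2 * i / d)
  emb <- vapply(value, function(v) {
    e <- numeric(d)
    e[2 * i + 1] <- sin(v * freq)
    e[2 * i + 2] <- cos(v * freq)
    e
  }, numeric(d))
  if (length(value) == 1L) as.vector(emb) else emb
}

#' Additive per-channel conditional biasing of a feature map
#'
#' Injects a covariate embedding into a convolutional feature map by adding
#' one scalar per channel: `out[ , , ch, n] = features[ , , ch, n] + b[ch, n]`
#' where `b = projection(embedding)`. Each residual block owns its own
#' projection so conditioning can be fitted per layer; the bias is applied
#' before the block's group normalization.
#'
#' @param features array `(H, W, C, N)` or `(H, W, C)` feature map.
#' @param embedding embedding vector (length `d`) or `d x N` matrix.
#' @param projection a function mapping the embedding to a length-`C` vector
#'   (or `C x N` matrix); defaults to identity, in which case the embedding
#'   length must equal `C`.
#' @return feature map of the same shape with the bias added.
#' @export
conditional_bias <- function(features, embedding, projection = identity) {
  d3 <- length(dim(features)) == 3L
  if (d3) dim(features) <- c(dim(features), 1L)
  dm <- dim(features)
  b <- projection(embedding)
  if (is.null(dim(b))) {
    if (length(b) != dm[3])
      stop(sprintf("projection output has length %d but feature map has %d channels",
                   length(b), dm[3]))
    b <- matrix(b, dm[3], dm[4])
  }
  if (nrow(b) != dm[3] || ncol(b) != dm[4])
    stop(sprintf("projection output has length %d but feature map has %d channels",
                 nrow(b), dm[3]))
  out <- features + rep(as.vector(b), each = dm[1] * dm[2])
  dim(out) <- dm
  if (d3) dim(out) <- dm[1:3]
  out
}

# Two-layer projection head used inside networks: linear -> lrelu -> linear.
# Returns a list of parameter nodes; apply with cond_proj_forward.
# zero_out starts the projection silent (output layer at zero): the
# conditioning then grows only along directions the loss rewards, instead of
# injecting noise the early optimization may learn to suppress for good.
cond_proj_init <- function(d, hidden, channels, zero_out = FALSE) {
  g2 <- if (zero_out) 0 else sqrt(2 / hidden)
  list(w1 = ad_param(matrix(rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)),
       b1 = ad_param(numeric(hidden)),
       w2 = ad_param(matrix(rnorm(hidden * channels, sd = g2), hidden,
                            channels)),
       b2 = ad_param(numeric(channels)))
}

# emb: adnode or matrix (d, N). Returns adnode (channels, N).
cond_proj_forward <- function(proj, emb) {
  h <- op_lrelu(op_linear(as_ad(emb), proj$w1, proj$b1), 0.2)
  op_linear(h, proj$w2, proj$b2)
}
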