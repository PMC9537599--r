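# Generator and critic definitions.
#
# The generator is a U-Net of residual blocks with single-head spatial
# self-attention at the coarsest resolutions, in the style of the backbones
# used by recent diffusion models. Every residual block receives the
# covariate through additive per-channel conditional biasing applied before
# its first group normalization. The network emits a residual mapping bounded
# to [-1, 1] by tanh; the synthesized image is clip(x + mapping, 0, 1).

#' Network configuration
#'
#' @param image_size input side length (square images); must be divisible by
#'   `2^(levels - 1)`.
#' @param levels number of resolution levels (default 4).
#' @param base_width channels at the finest level (default 32).
#' @param channel_mults per-level channel multipliers.
#' @param blocks_per_level residual blocks per level (default 2).
#' @param attn_levels encoder levels (1 = finest) that get self-attention;
#'   defaults to the two coarsest.
#' @param emb_dim sinusoidal embedding length.
#' @param proj_hidden hidden width of the per-block conditioning projections.
#' @param groups group-normalization groups.
#' @param head_gain multiplier on the initialization of the output convolution;
#'   small values start the generator close to the identity mapping.
#' @return a list of class `cardiosynth_net_config`.
#' @export
net_config <- function(image_size = 128L, levels = 4L, base_width = 32L,
                       channel_mults = c(1, 2, 2, 4), blocks_per_level = 2L,
                       attn_levels = NULL, emb_dim = 64L, proj_hidden = 64L,
                       groups = 8L, head_gain = 0.2) {
  stopifnot(length(channel_mults) == levels)
  if (image_size %% 2^(levels - 1) != 0)
    stop("image_size must be divisible by 2^(levels - 1)")
  if (is.null(attn_levels)) attn_levels <- c(levels - 1L, levels)
  widths <- as.integer(base_width * channel_mults)
  if (any(widths %% groups != 0))
    stop("all channel widths must be divisible by the number of groups")
  structure(list(image_size = as.integer(image_size), levels = as.integer(levels),
                 base_width = as.integer(base_width), channel_mults = channel_mults,
                 widths = widths, blocks_per_level = as.integer(blocks_per_level),
                 attn_levels = as.integer(attn_levels), emb_dim = as.integer(emb_dim),
                 proj_hidden = as.integer(proj_hidden), groups = as.integer(groups),
                 head_gain = head_gain),
            class = "cardiosynth_net_config")
}

conv_init <- function(kh, kw, cin, cout, gain = 1) {
  list(w = ad_param(array(rnorm(kh * kw * cin * cout,
                                sd = gain * sqrt(2 / (kh * kw * cin))),
                          c(kh, kw, cin, cout))),
       b = ad_param(numeric(cout)))
}

gn_init <- function(c) list(gamma = ad_param(rep(1, c)), beta = ad_param(numeric(c)))

resblock_init <- function(cin, cout, cfg) {
  list(proj = cond_proj_init(cfg$emb_dim, cfg$proj_hidden, cin),
       gn1 = gn_init(cin), conv1 = conv_init(3, 3, cin, cout),
       gn2 = gn_init(cout), conv2 = conv_init(3, 3, cout, cout),
       skip = if (cin != cout) conv_init(1, 1, cin, cout) else NULL)
}

attnblock_init <- function(c) {
  g <- 1 / sqrt(c)
  list(gn = gn_init(c),
       wq = ad_param(matrix(rnorm(c * c, sd = g), c, c)),
       wk = ad_param(matrix(rnorm(c * c, sd = g), c, c)),
       wv = ad_param(matrix(rnorm(c * c, sd = g), c, c)),
       wo = ad_param(matrix(rnorm(c * c, sd = g * 0.2), c, c)))
}

resblock_fwd <- function(blk, h, emb, cfg) {
  t <- op_bias_cn(h, cond_proj_forward(blk$proj, emb))
  t <- op_group_norm(t, blk$gn1$gamma, blk$gn1$beta, cfg$groups)
  t <- op_silu(t)
  t <- op_conv(t, blk$conv1$w, blk$conv1$b, 1L, 1L)
  t <- op_group_norm(t, blk$gn2$gamma, blk$gn2$beta, cfg$groups)
  t <- op_silu(t)
  t <- op_conv(t, blk$conv2$w, blk$conv2$b, 1L, 1L)
  s <- if (is.null(blk$skip)) h else op_conv(h, blk$skip$w, blk$skip$b, 1L, 0L)
  op_add(s, t)
}

attnblock_fwd <- function(blk, h, cfg) {
  t <- op_group_norm(h, blk$gn$gamma, blk$gn$beta, cfg$groups)
  op_add(h, op_attention(t, blk$wq, blk$wk, blk$wv, blk$wo))
}

#' Construct a conditional residual U-Net generator
#'
#' @param config a [net_config()].
#' @param seed integer seed controlling parameter initialization.
#' @return an object of class `cardiosynth_generator`.
#' @export
generator_net <- function(config = net_config(), seed = 1L) {
  cfg <- config
  with_seed(seed, "generator_init", {
    w <- cfg$widths
    L <- cfg$levels
    enc <- vector("list", L)
    for (i in seq_len(L)) {
      cin_lev <- if (i == 1) w[1] else w[i]
      blocks <- vector("list", cfg$blocks_per_level)
      for (b in seq_len(cfg$blocks_per_level))
        blocks[[b]] <- resblock_init(cin_lev, w[i], cfg)
      enc[[i]] <- list(
        blocks = blocks,
        attn = if (i %in% cfg$attn_levels) attnblock_init(w[i]) else NULL,
        down = if (i < L) conv_init(3, 3, w[i], w[i + 1]) else NULL)
    }
    mid <- list(b1 = resblock_init(w[L], w[L], cfg),
                attn = attnblock_init(w[L]),
                b2 = resblock_init(w[L], w[L], cfg))
    dec <- vector("list", L - 1)
    for (i in seq_len(L - 1)) {
      lev <- L - i                      # decoder level produced (L-1 .. 1)
      blocks <- vector("list", cfg$blocks_per_level)
      blocks[[1]] <- resblock_init(2L * w[lev], w[lev], cfg)
      if (cfg$blocks_per_level > 1)
        for (b in 2:cfg$blocks_per_level) blocks[[b]] <- resblock_init(w[lev], w[lev], cfg)
      dec[[i]] <- list(up = conv_init(3, 3, w[lev + 1], w[lev]), blocks = blocks)
    }
    gen <- list(cfg = cfg,
                stem = conv_init(3, 3, 1, w[1]),
                enc = enc, mid = mid, dec = dec,
                head = list(gn = gn_init(w[1]),
                            conv = conv_init(3, 3, w[1], 1, gain = cfg$head_gain)),
                seed = as.integer(seed))
    class(gen) <- "cardiosynth_generator"
    gen
  })
}

# Recursively collect parameter nodes from a nested module list.
params_of <- function(x) {
  if (inherits(x, "adnode")) return(if (x$param) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, params_of)))
  list()
}

# Core tape forward: x is an adnode (H, W, 1, N); a_d a numeric vector (N).
# Returns list(mapping = adnode in [-1,1], output = adnode in [0,1]).
generator_apply <- function(gen, x, a_d) {
  cfg <- gen$cfg
  N <- dim(x$v)[4]
  emb <- ad_const(matrix(sinusoidal_embed(a_d, cfg$emb_dim), cfg$emb_dim, N))
  h <- op_conv(x, gen$stem$w, gen$stem$b, 1L, 1L)
  skips <- vector("list", cfg$levels)
  for (i in seq_len(cfg$levels)) {
    lev <- gen$enc[[i]]
    for (blk in lev$blocks) h <- resblock_fwd(blk, h, emb, cfg)
    if (!is.null(lev$attn)) h <- attnblock_fwd(lev$attn, h, cfg)
    skips[[i]] <- h
    if (!is.null(lev$down)) h <- op_conv(h, lev$down$w, lev$down$b, 2L, 1L)
  }
  h <- resblock_fwd(gen$mid$b1, h, emb, cfg)
  h <- attnblock_fwd(gen$mid$attn, h, cfg)
  h <- resblock_fwd(gen$mid$b2, h, emb, cfg)
  for (i in seq_along(gen$dec)) {
    lev <- cfg$levels - i
    h <- op_upsample2(h)
    h <- op_conv(h, gen$dec[[i]]$up$w, gen$dec[[i]]$up$b, 1L, 1L)
    h <- op_concat_c(h, skips[[lev]])
    for (blk in gen$dec[[i]]$blocks) h <- resblock_fwd(blk, h, emb, cfg)
  }
  h <- op_group_norm(h, gen$head$gn$gamma, gen$head$gn$beta, cfg$groups)
  h <- op_silu(h)
  m <- op_tanh(op_conv(h, gen$head$conv$w, gen$head$conv$b, 1L, 1L))
  xt <- op_clip(op_add(x, m), 0, 1)
  list(mapping = m, output = xt)
}

# Coerce user images (matrix, (H,W,N) stack, or (H,W,1,N)) to (H,W,1,N).
as_batch <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) {
    d <- dim(x)
    x <- array(x, c(d[1], d[2], 1L, d[3]))
  }
  stopifnot(length(dim(x)) == 4L, dim(x)[3] == 1L)
  x
}

validate_image_input <- function(x, cfg) {
  d <- dim(x)
  if (d[1] != d[2]) stop("input images must be square")
  if (d[1] %% 2^(cfg$levels - 1) != 0)
    stop(sprintf("image size %d is not divisible by 2^%d", d[1], cfg$levels - 1))
  if (min(x) < -1e-6 || max(x) > 1 + 1e-6)
    stop("input images must be normalized to [0, 1]")
  invisible(TRUE)
}

#' Synthesize covariate-shifted images
#'
#' Runs the generator on one image or a stack of images with the requested
#' covariate gap(s). The generator produces a residual mapping `m` bounded to
#' `[-1, 1]`; the synthesized image is `clip(x + m, 0, 1)`.
#'
#' @param generator a [generator_net()] (possibly trained).
#' @param x matrix `(H, W)` or array `(H, W, N)` of images in `[0, 1]`.
#' @param a_d covariate gap(s): scalar, or vector of length `N`.
#' @return an object of class `synthesis_result`: list with `input`, `mapping`
#'   (in `[-1, 1]`) and `output = clip(input + mapping, 0, 1)`, shaped like `x`.
#' @export
generator_forward <- function(generator, x, a_d) {
  xb <- as_batch(x)
  validate_image_input(xb, generator$cfg)
  N <- dim(xb)[4]
  if (length(a_d) == 1L) a_d <- rep(a_d, N)
  stopifnot(length(a_d) == N)
  res <- generator_apply(generator, ad_const(xb), a_d)
  shape_back <- function(v) {
    if (is.matrix(x)) matrix(v, dim(xb)[1], dim(xb)[2])
    else array(v, c(dim(xb)[1], dim(xb)[2], N))
  }
  structure(list(input = x, mapping = shape_back(res$mapping$v),
                 output = shape_back(res$output$v), a_d = a_d),
            class = "synthesis_result")
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("synthesis_result: %d image(s), mapping range [%.3f, %.3f]\n",
              if (is.matrix(x$input)) 1L else dim(x$input)[3],
              min(x$mapping), max(x$mapping)))
  invisible(x)
}

# ---- small plain CNNs (covariate regressor / feature extractor) -------------

# A compact convolutional network: stride-2 conv stack with residual 3x3
# stages, global average pooling and a dense head. Used for the covariate
# regressor and the feature extractor behind the Frechet distance.
convnet_init <- function(widths = c(8, 16, 32), out_dim = 1L, seed = 1L,
                         in_ch = 1L) {
  with_seed(seed, "convnet_init", {
    layers <- vector("list", length(widths))
    cin <- in_ch
    for (i in seq_along(widths)) {
      layers[[i]] <- list(down = conv_init(4, 4, cin, widths[i]),
                          conv = conv_init(3, 3, widths[i], widths[i]))
      cin <- widths[i]
    }
    list(layers = layers,
         fc = list(w = ad_param(matrix(rnorm(cin * out_dim, sd = sqrt(1 / cin)),
                                       cin, out_dim)),
                   b = ad_param(numeric(out_dim))),
         widths = widths, out_dim = out_dim)
  })
}

# Returns list(out = (out_dim, N) node, features = (C, N) node).
convnet_fwd <- function(net, x) {
  h <- as_ad(x)
  for (ly in net$layers) {
    h <- op_lrelu(op_conv(h, ly$down$w, ly$down$b, 2L, 1L), 0.1)
    h <- op_add(h, op_lrelu(op_conv(h, ly$conv$w, ly$conv$b, 1L, 1L), 0.1))
  }
  f <- op_gap(h)
  list(out = op_linear(f, net$fc$w, net$fc$b), features = f)
}
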