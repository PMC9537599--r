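# Conditional critic (WGAN discriminator).
#
# The critic is a normalization-free strided convolutional encoder with
# leaky-ReLU activations, additive per-channel conditional biasing of every
# layer (from a sinusoidal embedding of the presented covariate), adaptive
# mean pooling and a dense head producing one scalar score per image.
# Keeping the critic piecewise linear in its input makes the WGAN-GP
# second-order term tractable in closed form: with the activation pattern
# fixed (exact almost everywhere), the input gradient is a composition of
# linear maps, and the parameter gradient of the penalty is obtained by
# backpropagating through that composition. Normalization layers are omitted
# on purpose: the gradient penalty is defined per sample and batch-coupled
# statistics would invalidate it.

#' Construct a conditional critic network
#'
#' @inheritParams generator_net
#' @return an object of class `cardiosynth_critic`.
#' @export
critic_net <- function(config = net_config(), seed = 1L) {
  cfg <- config
  with_seed(seed, "critic_init", {
    w <- cfg$widths
    L <- cfg$levels
    layers <- vector("list", L)
    cin <- 1L
    for (i in seq_len(L)) {
      stride <- if (i == 1) 1L else 2L
      k <- if (i == 1) 3L else 4L
      layers[[i]] <- list(
        w = ad_param(array(rnorm(k * k * cin * w[i], sd = sqrt(2 / (k * k * cin))),
                           c(k, k, cin, w[i]))),
        b = ad_param(numeric(w[i])),
        proj = cond_proj_init(cfg$emb_dim, cfg$proj_hidden, w[i]),
        stride = stride, k = k, pad = 1L)
      cin <- w[i]
    }
    cr <- list(cfg = cfg, layers = layers, alpha = 0.2,
               head = list(w = ad_param(rnorm(cin, sd = sqrt(1 / cin))),
                           b = ad_param(0)),
               seed = as.integer(seed))
    class(cr) <- "cardiosynth_critic"
    cr
  })
}

# Forward pass. x: (H, W, 1, N); a: covariate vector (N).
# Returns list(score, cache) where cache holds every intermediate needed by
# the backward passes.
critic_apply <- function(cr, x, a) {
  N <- dim(x)[4]
  emb <- matrix(sinusoidal_embed(a, cr$cfg$emb_dim), cr$cfg$emb_dim, N)
  hs <- list(x)          # hs[[l]] is the input of layer l
  masks <- vector("list", length(cr$layers))
  mlps <- vector("list", length(cr$layers))
  h <- x
  for (l in seq_along(cr$layers)) {
    ly <- cr$layers[[l]]
    z <- conv2d_fwd(h, ly$w$v, ly$stride, ly$pad)
    d <- dim(z)
    h1pre <- crossprod(ly$proj$w1$v, emb) + ly$proj$b1$v
    m1 <- ifelse(h1pre > 0, 1, 0.2)
    h1 <- h1pre * m1
    cb <- crossprod(ly$proj$w2$v, h1) + ly$proj$b2$v      # (C, N)
    z <- z + rep(ly$b$v, each = d[1] * d[2]) +
      rep(as.vector(cb), each = d[1] * d[2])
    if (!all(is.finite(z)))
      stop(sprintf("non-finite activations in critic layer %d", l))
    mk <- ifelse(z > 0, 1, cr$alpha)
    h <- z * mk
    dim(h) <- d
    masks[[l]] <- mk
    mlps[[l]] <- list(h1 = h1, m1 = m1)
    hs[[l + 1]] <- h
  }
  dlast <- dim(h)
  hw <- dlast[1] * dlast[2]
  pooled <- matrix(colMeans(matrix(h, nrow = hw)), nrow = dlast[3])  # (C, N)
  score <- drop(crossprod(pooled, cr$head$w$v)) + cr$head$b$v
  list(score = score, cache = list(hs = hs, masks = masks, mlps = mlps,
                                   pooled = pooled, emb = emb, N = N))
}

#' Score images with the conditional critic
#'
#' @param critic a [critic_net()].
#' @param x matrix `(H, W)` or array of images in `[0, 1]`.
#' @param a the covariate presented with each image: the true covariate for
#'   real images, the target covariate for synthesized ones.
#' @return numeric vector of finite scalar scores, one per image.
#' @export
critic_forward <- function(critic, x, a) {
  xb <- as_batch(x)
  validate_image_input(xb, critic$cfg)
  N <- dim(xb)[4]
  if (length(a) == 1L) a <- rep(a, N)
  stopifnot(length(a) == N)
  critic_apply(critic, xb, a)$score
}

# Backward pass for the linear score terms. dscore: (N). When accumulate is
# TRUE, parameter gradients are added into the param nodes' $grad slots.
# Returns the gradient with respect to the input (per sample, scaled by
# dscore) when want_input = TRUE.
critic_backward <- function(cr, cache, dscore, accumulate = TRUE,
                            want_input = FALSE) {
  L <- length(cr$layers)
  hlast <- cache$hs[[L + 1]]
  d <- dim(hlast)
  hw <- d[1] * d[2]
  if (accumulate) {
    ad_accum(cr$head$w, drop(cache$pooled %*% dscore))
    ad_accum(cr$head$b, sum(dscore))
  }
  # d(sum dscore_n * score_n)/d h_L
  dpool <- outer(cr$head$w$v, dscore)                     # (C, N)
  dh <- array(rep(as.vector(dpool) / hw, each = hw), d)
  for (l in L:1) {
    ly <- cr$layers[[l]]
    dz <- dh * cache$masks[[l]]
    dd <- dim(dz)
    if (accumulate) {
      dzm <- matrix(dz, nrow = dd[1] * dd[2])
      dcb <- matrix(colSums(dzm), nrow = dd[3])           # (C, N)
      ad_accum(ly$b, rowSums(dcb))
      mlp <- cache$mlps[[l]]
      ad_accum(ly$proj$w2, mlp$h1 %*% t(dcb))
      ad_accum(ly$proj$b2, rowSums(dcb))
      dh1 <- (ly$proj$w2$v %*% dcb) * mlp$m1
      ad_accum(ly$proj$w1, cache$emb %*% t(dh1))
      ad_accum(ly$proj$b1, rowSums(dh1))
      ad_accum(ly$w, conv2d_bwd_weight(cache$hs[[l]], dz, ly$stride, ly$pad,
                                       ly$k, ly$k))
    }
    if (l > 1 || want_input) {
      din <- dim(cache$hs[[l]])
      dh <- conv2d_bwd_input(dz, ly$w$v, ly$stride, ly$pad, din[1], din[2])
    }
  }
  if (want_input) dh else invisible(NULL)
}

# Per-sample gradient of each sample's own score with respect to its input:
# the critic is piecewise linear, so this is exact given the cached masks.
critic_input_grad <- function(cr, cache) {
  critic_backward(cr, cache, rep(1, cache$N), accumulate = FALSE,
                  want_input = TRUE)
}

# Gradient-penalty value and (optionally) its exact parameter gradient.
#
# Let g = d score / d input (per sample). The penalty is
# mean_n (||g_n||_2 - 1)^2. With activation masks fixed, g is produced by the
# linear chain u_L = poolback(w_head); t_l = u_l * mask_l;
# u_{l-1} = convT_l(t_l); g = u_0. Differentiating the penalty through this
# chain gives exact parameter gradients for the convolution weights and the
# head: biases and conditioning projections receive zero (their second-order
# contribution vanishes almost everywhere for piecewise-linear activations).
critic_gp_chain <- function(cr, cache, scale = 0, accumulate = FALSE) {
  L <- length(cr$layers)
  N <- cache$N
  dlast <- dim(cache$hs[[L + 1]])
  hw <- dlast[1] * dlast[2]
  u <- array(rep(rep(cr$head$w$v / hw, each = hw), N), dlast)
  ts <- us <- vector("list", L)
  for (l in L:1) {
    ly <- cr$layers[[l]]
    us[[l]] <- u
    t_l <- u * cache$masks[[l]]
    ts[[l]] <- t_l
    din <- dim(cache$hs[[l]])
    u <- conv2d_bwd_input(t_l, ly$w$v, ly$stride, ly$pad, din[1], din[2])
  }
  g <- u                                              # (H, W, 1, N)
  gm <- matrix(g, ncol = N)
  norms <- sqrt(colSums(gm^2))
  penalty <- mean((norms - 1)^2)
  if (accumulate && scale != 0) {
    r <- 2 * (norms - 1) / pmax(norms, 1e-12) / N * scale
    cvec <- gm * rep(r, each = nrow(gm))
    cc <- array(cvec, dim(g))
    for (l in seq_len(L)) {
      ly <- cr$layers[[l]]
      ad_accum(ly$w, conv2d_bwd_weight(cc, ts[[l]], ly$stride, ly$pad,
                                       ly$k, ly$k))
      cc <- conv2d_fwd(cc, ly$w$v, ly$stride, ly$pad) * cache$masks[[l]]
      dim(cc) <- dim(us[[l]])
    }
    dw <- rowSums(matrix(colMeans(matrix(cc, nrow = hw)), nrow = dlast[3]))
    ad_accum(cr$head$w, dw)
  }
  penalty
}

# Tape op exposing critic scores to the generator's graph: gradients flow
# into the synthesized images but not into the critic parameters (alternating
# optimization).
op_critic_score <- function(cr, xnode, a) {
  fw <- critic_apply(cr, xnode$v, a)
  ad_node(fw$score, list(xnode), function(g) {
    gin <- critic_input_grad(cr, fw$cache)
    d <- dim(gin)
    gin <- gin * rep(g, each = d[1] * d[2] * d[3])
    list(gin)
  })
}
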