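test_that("tape gradients of a composed network match finite differences", {
  set.seed(42)
  cfg <- net_config(image_size = 8, levels = 2, base_width = 8,
                    channel_mults = c(1, 2), blocks_per_level = 1,
                    attn_levels = 2, emb_dim = 8, proj_hidden = 8, groups = 4,
                    head_gain = 1)
  gen <- generator_net(cfg, seed = 3)
  ps <- ns$params_of(gen)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  a_d <- c(5, -10)
  lossfun <- function() {
    out <- ns$generator_apply(gen, ns$ad_const(x), a_d)
    ns$op_mean(ns$op_mul(out$output, out$output))
  }
  L <- lossfun()
  ns$ad_zero_grads(ps)
  ns$ad_backward(L)
  eps <- 1e-6
  for (pi in sample(seq_along(ps), 10)) {
    p <- ps[[pi]]
    k <- sample(length(p$v), 1)
    g_an <- if (is.null(p$grad)) 0 else as.vector(p$grad)[k]
    old <- p$v[k]
    p$v[k] <- old + eps; Lp <- lossfun()$v
    p$v[k] <- old - eps; Lm <- lossfun()$v
    p$v[k] <- old
    g_fd <- (Lp - Lm) / (2 * eps)
    expect_equal(g_an, g_fd, tolerance = 1e-5)
  }
})

test_that("critic backward and analytic penalty gradients match finite differences", {
  set.seed(7)
  cfg <- net_config(image_size = 8, levels = 2, base_width = 8,
                    channel_mults = c(1, 2), blocks_per_level = 1,
                    emb_dim = 8, proj_hidden = 8, groups = 4)
  cr <- critic_net(cfg, seed = 11)
  cp <- ns$params_of(cr)
  x <- array(runif(8 * 8 * 3), c(8, 8, 1, 3))
  a <- c(50, 60, 70)
  lam <- 10
  lossval <- function() {
    fw <- ns$critic_apply(cr, x, a)
    mean(fw$score) + lam * ns$critic_gp_chain(cr, fw$cache)
  }
  fw <- ns$critic_apply(cr, x, a)
  ns$ad_zero_grads(cp)
  ns$critic_backward(cr, fw$cache, rep(1 / 3, 3))
  ns$critic_gp_chain(cr, fw$cache, scale = lam, accumulate = TRUE)
  eps <- 1e-6
  for (pi in seq_along(cp)) {
    p <- cp[[pi]]
    k <- sample(length(p$v), 1)
    g_an <- if (is.null(p$grad)) 0 else as.vector(p$grad)[k]
    old <- p$v[k]
    p$v[k] <- old + eps; Lp <- lossval()
    p$v[k] <- old - eps; Lm <- lossval()
    p$v[k] <- old
    expect_equal(g_an, (Lp - Lm) / (2 * eps), tolerance = 1e-4)
  }
  # per-sample input gradient
  gin <- ns$critic_input_grad(cr, fw$cache)
  expect_true(all(is.finite(gin)))
  for (kk in c(3, 57, 140)) {
    old <- x[kk]
    x[kk] <- old + eps
    sp <- sum(ns$critic_apply(cr, x, a)$score)
    x[kk] <- old - eps
    sm <- sum(ns$critic_apply(cr, x, a)$score)
    x[kk] <- old
    expect_equal(as.vector(gin)[kk], (sp - sm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("AdamW decouples weight decay from the gradient step", {
  p <- ns$ad_param(c(1, -2))
  st <- ns$adamw_init(list(p))
  p$grad <- c(0, 0)
  ns$adamw_step(list(p), st, lr = 0.1, weight_decay = 0.5)
  # zero gradient: pure decay p <- p - lr * wd * p
  expect_equal(p$v, c(1, -2) * (1 - 0.1 * 0.5))
})
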