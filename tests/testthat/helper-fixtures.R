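# Shared fixtures: tiny network configurations, hand-built degenerate
# networks (identity generator, constant and linear critics) and memoized
# phantom cohorts. Everything is generated in code at test time.

ns <- asNamespace("cardiosynth")

tiny_cfg <- function(size = 16L, base = 8L) {
  net_config(image_size = size, levels = 3L, base_width = base,
             channel_mults = c(1, 2, 4), blocks_per_level = 1L,
             attn_levels = 3L, emb_dim = 16L, proj_hidden = 16L, groups = 8L)
}

# Generator whose mapping is exactly 0 (identity synthesis): zero the output
# convolution.
identity_generator <- function(cfg = tiny_cfg(), seed = 1L) {
  gen <- generator_net(cfg, seed)
  gen$head$conv$w$v[] <- 0
  gen$head$conv$b$v[] <- 0
  gen
}

# Generator with constant mapping `shift` regardless of input and gap: the
# head group-norm gain is zeroed so the output conv sees zeros and its bias
# sets the mapping through tanh.
constant_shift_generator <- function(shift, cfg = tiny_cfg(), seed = 1L) {
  gen <- generator_net(cfg, seed)
  gen$head$gn$gamma$v[] <- 0
  gen$head$gn$beta$v[] <- 0
  gen$head$conv$w$v[] <- 0
  gen$head$conv$b$v[] <- atanh(shift)
  gen
}

# Critic with every parameter zeroed: D == 0 for all inputs.
constant_critic <- function(cfg = tiny_cfg(), seed = 1L) {
  cr <- critic_net(cfg, seed)
  for (p in ns$params_of(cr)) p$v[] <- 0
  cr
}

# Critic that is exactly linear, D(x) = <w_eff, x> + const with
# ||w_eff|| = norm, on images in [0, 1]:
# single level, center-tap convolution, large positive bias keeping every
# leaky-ReLU in its linear (slope 1) regime, zeroed conditioning.
linear_critic <- function(size = 4L, norm = 3) {
  cfg <- net_config(image_size = size, levels = 1L, base_width = 8L,
                    channel_mults = 1, blocks_per_level = 1L, attn_levels = 1L,
                    emb_dim = 8L, proj_hidden = 8L, groups = 8L)
  cr <- critic_net(cfg, seed = 1L)
  ly <- cr$layers[[1]]
  ly$w$v[] <- 0
  ly$w$v[2, 2, 1, 1] <- 1            # center tap, first channel only
  ly$b$v[] <- 10                     # keeps pre-activations positive on [0,1]
  for (p in ns$params_of(ly$proj)) p$v[] <- 0
  cr$head$w$v[] <- 0
  # D = head_w[1] * mean(x + 10) => w_eff = head_w[1]/HW per pixel,
  # ||w_eff|| = head_w[1]/sqrt(HW)
  cr$head$w$v[1] <- norm * size
  cr$head$b$v[] <- 0
  cr
}

# Memoized tiny cohorts on disk (tempdir), keyed by parameters.
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(n = 40L, size = 32L, noise_sd = 0.02,
                           jitter = TRUE, seed = 7L, mode = "age") {
  key <- paste(n, size, noise_sd, jitter, seed, mode, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), paste0("cohort_", key))
  co <- generate_cohort(n, dir, image_size = size, covariate_mode = mode,
                        noise_sd = noise_sd, jitter = jitter, rng_seed = seed)
  .fixture_env[[key]] <- co
  co
}

# Finite-difference gradient of f at x (central differences).
fd_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Oracle regressor for MAE bookkeeping tests: images are constant matrices
# whose value encodes the covariate as value * 100.
oracle_regressor <- function() structure(list(), class = "oracle_regressor")
predict.oracle_regressor <- function(object, newdata, ...) {
  xb <- ns$as_batch(newdata)
  apply(xb, 4, mean) * 100
}
registerS3method("predict", "oracle_regressor", predict.oracle_regressor,
                 envir = asNamespace("stats"))
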