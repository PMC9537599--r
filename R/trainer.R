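# Preprocessing, augmentation, schedule and the WGAN-GP training loop.

#' Training configuration
#'
#' Defaults follow the full-scale protocol (300 epochs, batch 12, AdamW at
#' learning rate and weight decay 1e-4, betas 0.9/0.999, 20 warm-up epochs
#' with 50 critic updates per generator update, then 5). Toy-scale runs
#' override `epochs`, `net` and the preprocessing fields.
#'
#' @param epochs,batch_size,warmup_epochs,critic_updates_warmup,critic_updates_main
#'   loop controls.
#' @param learning_rate,weight_decay,betas AdamW settings (both networks).
#' @param crop_pixels_x total columns removed by the preprocessing crop (0
#'   disables the crop).
#' @param target_size side length images are resized to.
#' @param gap_min,gap_max training covariate-gap sampling range (years).
#' @param age_range cohort covariate range used to truncate sampled gaps.
#' @param weights a [loss_weights()].
#' @param net a [net_config()].
#' @param augment logical; apply random intensity augmentation during training.
#' @param critic_input_noise standard deviation of Gaussian instance noise
#'   added to both real and generated images before they reach the critic
#'   (training only). Masks low-amplitude generator fingerprints so the
#'   critic must discriminate on structure rather than synthesis texture.
#' @param ema_decay exponential-moving-average decay for the generator
#'   weights used at evaluation time (0, the default, disables). The averaged
#'   generator suppresses step-to-step update noise, but also dampens a
#'   covariate response that is still being learned, so it is an option
#'   rather than the default.
#' @param drift small coefficient on `mean(D(x)^2)` (real and generated
#'   branches) added to the critic loss to pin the critic's score scale: the
#'   Wasserstein objective is invariant to score offsets, which otherwise
#'   lets the scale run away.
#' @param seed root seed for initialization and the training stream.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 12L, warmup_epochs = 20L,
                         critic_updates_warmup = 50L, critic_updates_main = 5L,
                         learning_rate = 1e-4, weight_decay = 1e-4,
                         betas = c(0.9, 0.999), crop_pixels_x = 90L,
                         target_size = 128L, gap_min = -25, gap_max = 25,
                         age_range = c(45, 82), weights = loss_weights(),
                         net = net_config(image_size = target_size),
                         augment = TRUE, drift = 1e-3,
                         critic_input_noise = 0.02, ema_decay = 0,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, warmup_epochs >= 0,
            critic_updates_warmup >= 1, critic_updates_main >= 1,
            net$image_size == target_size)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 warmup_epochs = as.integer(warmup_epochs),
                 critic_updates_warmup = as.integer(critic_updates_warmup),
                 critic_updates_main = as.integer(critic_updates_main),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 betas = betas, crop_pixels_x = as.integer(crop_pixels_x),
                 target_size = as.integer(target_size), gap_min = gap_min,
                 gap_max = gap_max, age_range = age_range, weights = weights,
                 net = net, augment = augment, drift = drift,
                 critic_input_noise = critic_input_noise,
                 ema_decay = ema_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Preprocess a raw grayscale image
#'
#' Center-crops `crop_pixels_x` columns in total (the extra column of an odd
#' split is removed on the left), resizes bilinearly to
#' `target_size x target_size` and rescales intensities linearly to `[0, 1]`.
#' Constant images map to all zeros.
#'
#' @param image numeric matrix.
#' @param crop_pixels_x total columns to remove (default 90).
#' @param target_size output side length (default 128).
#' @return matrix `target_size x target_size` in `[0, 1]`.
#' @export
preprocess <- function(image, crop_pixels_x = 90L, target_size = 128L) {
  stopifnot(is.matrix(image))
  w <- ncol(image)
  if (crop_pixels_x > 0) {
    if (w <= crop_pixels_x)
      stop(sprintf("image width %d is not larger than the %d-pixel crop",
                   w, crop_pixels_x))
    left <- ceiling(crop_pixels_x / 2)
    right <- crop_pixels_x - left
    image <- image[, (left + 1):(w - right), drop = FALSE]
  }
  if (nrow(image) != target_size || ncol(image) != target_size) {
    image <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                                w = target_size,
                                                h = target_size))
  }
  rng <- range(image)
  if (rng[2] - rng[1] < .Machine$double.eps) return(matrix(0, target_size,
                                                           target_size))
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Random intensity augmentation
#'
#' Applies, each with independent probability 1/2: a multiplicative low-order
#' polynomial bias field, a monotone histogram remap through jittered control
#' points, and a gamma-style contrast adjustment; the output is re-clipped to
#' `[0, 1]`. Deterministic given the seed.
#'
#' @param image matrix in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return augmented matrix in `[0, 1]`.
#' @export
augment <- function(image, rng_seed = 1L) {
  stopifnot(is.matrix(image), min(image) >= -1e-9, max(image) <= 1 + 1e-9)
  with_seed(rng_seed, "augment", {
    h <- nrow(image); w <- ncol(image)
    if (runif(1) < 0.5) {                     # polynomial bias field
      u <- matrix(seq(-1, 1, length.out = h), h, w)
      v <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
      cf <- runif(5, -0.05, 0.05)
      field <- 1 + cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 +
        cf[5] * v^2
      image <- image * field
    }
    if (runif(1) < 0.5) {                     # monotone histogram remap
      k <- 5
      xk <- seq(0, 1, length.out = k)
      yk <- xk + c(0, runif(k - 2, -0.04, 0.04), 0)
      yk <- cummax(yk)                        # keep the remap monotone
      image <- matrix(approx(xk, yk, xout = pmin(pmax(image, 0), 1),
                             rule = 2)$y, h, w)
    }
    if (runif(1) < 0.5) {                     # gamma contrast
      g <- exp(runif(1, log(0.9), log(1.12)))
      image <- pmin(pmax(image, 0), 1)^g
    }
    pmin(pmax(image, 0), 1)
  })
}

#' Critic update schedule
#'
#' During the warm-up period the critic (discriminator) is updated 50 times
#' for every generator update; afterwards 5 times.
#'
#' @param epoch 0-based epoch index.
#' @param warmup_epochs length of the warm-up period (default 20).
#' @param updates_warmup,updates_main critic updates per generator update.
#' @return integer number of critic updates per generator step.
#' @export
critic_schedule <- function(epoch, warmup_epochs = 20L, updates_warmup = 50L,
                            updates_main = 5L) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  ifelse(epoch < warmup_epochs, as.integer(updates_warmup),
         as.integer(updates_main))
}

#' Sample a training pair and an independent real batch
#'
#' Draws source images with their true covariates, a covariate gap uniform on
#' `[gap_min, gap_max]` truncated so the target stays inside the cohort's
#' covariate range, and an independent real batch presented with its own true
#' covariates.
#'
#' @param cohort a cohort table.
#' @param gap_config list with `min`, `max` (defaults +-25).
#' @param rng_seed integer seed.
#' @param batch_size images per batch.
#' @param images optional preloaded `(H, W, N)` array aligned with the cohort
#'   rows; loaded from disk otherwise.
#' @param age_range covariate range used for the truncation.
#' @return list with `x` (source batch `(H,W,1,B)`), `pair` (a `covariate_pair`
#'   list of `a_s`, `a_t`, `a_d`), `x_real`, `a_real` and the sampled row
#'   indices.
#' @export
sample_training_pair <- function(cohort, gap_config = list(min = -25, max = 25),
                                 rng_seed = 1L, batch_size = 12L,
                                 images = NULL, age_range = c(45, 82)) {
  if (nrow(cohort) == 0) stop("empty cohort")
  with_seed(rng_seed, "pair_sampling", {
    draw_training_pair(cohort, images, batch_size, gap_config$min,
                       gap_config$max, age_range)
  })
}

# Internal: draws from the ambient RNG stream (the training loop owns it).
# The real batch is age-matched to the sampled targets (one draw among the
# nearest-age subjects) so the real and generated terms of the critic loss
# present the same covariate distribution; a systematic covariate mismatch
# would hand the critic an unbounded score direction that the gradient
# penalty, which only constrains image gradients, cannot touch.
draw_training_pair <- function(cohort, images, batch_size, gap_min, gap_max,
                               age_range, match_pool = 5L) {
  idx_s <- sample.int(nrow(cohort), batch_size, replace = TRUE)
  a_s <- cohort$age[idx_s]
  lo <- pmax(gap_min, age_range[1] - a_s)
  hi <- pmin(gap_max, age_range[2] - a_s)
  a_d <- runif(batch_size, lo, hi)
  idx_r <- vapply(a_s + a_d, function(target) {
    nn <- order(abs(cohort$age - target))[seq_len(min(match_pool,
                                                      nrow(cohort)))]
    nn[sample.int(length(nn), 1)]
  }, integer(1))
  fetch <- function(idx) {
    if (!is.null(images)) return(images[, , idx, drop = FALSE])
    base <- attr(cohort, "base_dir")
    out <- NULL
    for (i in seq_along(idx)) {
      im <- read_image(file.path(base, cohort$image_path[idx[i]]))
      if (is.null(out)) out <- array(0, c(nrow(im), ncol(im), length(idx)))
      out[, , i] <- im
    }
    out
  }
  xs <- fetch(idx_s)
  xr <- fetch(idx_r)
  d <- dim(xs)
  list(x = array(xs, c(d[1], d[2], 1L, d[3])),
       pair = covariate_pair(a_s, a_s + a_d),
       x_real = array(xr, c(d[1], d[2], 1L, d[3])),
       a_real = cohort$age[idx_r],
       idx_source = idx_s, idx_real = idx_r)
}

#' Source/target covariate pair
#'
#' @param a_s source covariate value(s); `a_t` target value(s).
#' @return list with `a_s`, `a_t` and the gap `a_d = a_t - a_s`.
#' @export
covariate_pair <- function(a_s, a_t) {
  structure(list(a_s = a_s, a_t = a_t, a_d = a_t - a_s),
            class = "covariate_pair")
}

# ---- checkpoints -------------------------------------------------------------

checkpoint_state <- function(gen, critic, opt_g, opt_c, config, epoch, history,
                             ema_values = NULL, pending_critic = 0L) {
  list(format = "cardiosynth_checkpoint_v1",
       config = config,
       epoch = epoch,
       history = history,
       pending_critic = pending_critic,
       gen_ema_values = ema_values,
       gen_values = lapply(params_of(gen), function(p) p$v),
       critic_values = lapply(params_of(critic), function(p) p$v),
       gen_adam = lapply(params_of(gen), function(p) list(m = p$m, v2 = p$v2)),
       critic_adam = lapply(params_of(critic),
                            function(p) list(m = p$m, v2 = p$v2)),
       opt_t = c(g = opt_g$t, c = opt_c$t),
       rng_state = get(".Random.seed", globalenv()))
}

restore_networks <- function(ckpt) {
  gen <- generator_net(ckpt$config$net, seed = ckpt$config$seed)
  critic <- critic_net(ckpt$config$net, seed = ckpt$config$seed + 1L)
  gp <- params_of(gen); cp <- params_of(critic)
  stopifnot(length(gp) == length(ckpt$gen_values),
            length(cp) == length(ckpt$critic_values))
  for (i in seq_along(gp)) gp[[i]]$v <- ckpt$gen_values[[i]]
  for (i in seq_along(cp)) cp[[i]]$v <- ckpt$critic_values[[i]]
  gen_ema <- NULL
  if (!is.null(ckpt$gen_ema_values)) {
    gen_ema <- generator_net(ckpt$config$net, seed = ckpt$config$seed)
    ge <- params_of(gen_ema)
    for (i in seq_along(ge)) ge[[i]]$v <- ckpt$gen_ema_values[[i]]
  }
  list(gen = gen, critic = critic, gen_ema = gen_ema)
}

#' Save / load a training checkpoint
#'
#' Checkpoints carry network parameters, optimizer moments, the full
#' configuration, the loss history and the RNG state, so a run can be resumed
#' with an identical subsequent trajectory.
#'
#' @param ckpt checkpoint list (as stored in a `cardiosynth_model`).
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!identical(ckpt$format, "cardiosynth_checkpoint_v1"))
    stop("not a cardiosynth checkpoint")
  ckpt
}

#' Reconstruct trained networks from a checkpoint
#'
#' @param ckpt a checkpoint (list or path).
#' @return list of class `cardiosynth_model` with `generator`, `critic`,
#'   `config`, `history` and the raw checkpoint.
#' @export
model_from_checkpoint <- function(ckpt) {
  if (is.character(ckpt)) ckpt <- load_checkpoint(ckpt)
  nets <- restore_networks(ckpt)
  structure(list(generator = if (!is.null(nets$gen_ema)) nets$gen_ema
                             else nets$gen,
                 generator_raw = nets$gen, critic = nets$critic,
                 config = ckpt$config, history = ckpt$history,
                 checkpoint = ckpt),
            class = "cardiosynth_model")
}

# ---- training loop -----------------------------------------------------------

load_training_images <- function(cohort, config) {
  imgs <- array(0, c(config$target_size, config$target_size, nrow(cohort)))
  base <- attr(cohort, "base_dir")
  for (i in seq_len(nrow(cohort))) {
    im <- read_image(file.path(base, cohort$image_path[i]))
    if (config$crop_pixels_x > 0 || nrow(im) != config$target_size ||
        ncol(im) != config$target_size)
      im <- preprocess(im, config$crop_pixels_x, config$target_size)
    imgs[, , i] <- im
  }
  imgs
}

augment_batch <- function(x, enabled) {
  if (!enabled) return(x)
  d <- dim(x)
  seeds <- sample.int(2^30, d[4])
  for (n in seq_len(d[4]))
    x[, , 1, n] <- augment(matrix(x[, , 1, n], d[1], d[2]), seeds[n])
  x
}

# One critic update; returns the loss components.
critic_update <- function(gen, critic, c_params, opt_c, batch, config) {
  w <- config$weights
  a_t <- batch$pair$a_t
  fwd <- generator_apply(gen, ad_const(batch$x), batch$pair$a_d)
  x_gen <- fwd$output$v
  N <- dim(x_gen)[4]
  ad_zero_grads(c_params)
  drift <- if (is.null(config$drift)) 0 else config$drift
  eta <- if (is.null(config$critic_input_noise)) 0 else config$critic_input_noise
  x_gen_n <- x_gen + array(rnorm(length(x_gen), 0, eta), dim(x_gen))
  x_real_n <- batch$x_real + array(rnorm(length(x_gen), 0, eta), dim(x_gen))
  fg <- critic_apply(critic, x_gen_n, a_t)
  critic_backward(critic, fg$cache, 1 / N + 2 * drift * fg$score / N)
  fr <- critic_apply(critic, x_real_n, batch$a_real)
  critic_backward(critic, fr$cache, -1 / N + 2 * drift * fr$score / N)
  eps <- runif(N)
  hw <- prod(dim(x_gen)[1:3])
  e <- rep(eps, each = hw)
  xhat <- array(e * x_real_n + (1 - e) * x_gen_n, dim(x_gen))
  fh <- critic_apply(critic, xhat, a_t)
  gp <- critic_gp_chain(critic, fh$cache, scale = w$lambda_gp,
                        accumulate = TRUE)
  opt_c <- adamw_step(c_params, opt_c, config$learning_rate,
                      config$weight_decay, config$betas[1], config$betas[2])
  core <- mean(fg$score) - mean(fr$score)
  list(opt = opt_c, critic_core = core, gp = gp,
       critic_total = core + w$lambda_gp * gp, x_gen = x_gen)
}

# One generator update on the given source batch.
generator_update <- function(gen, critic, g_params, opt_g, batch, config) {
  w <- config$weights
  ad_zero_grads(g_params)
  xnode <- ad_const(batch$x)
  fwd <- generator_apply(gen, xnode, batch$pair$a_d)
  eta <- if (is.null(config$critic_input_noise)) 0 else config$critic_input_noise
  gen_for_critic <- op_add(fwd$output,
                           array(rnorm(length(fwd$output$v), 0, eta),
                                 dim(fwd$output$v)))
  adv <- op_smul(op_mean(op_critic_score(critic, gen_for_critic,
                                         batch$pair$a_t)),
                 -1)
  back <- generator_apply(gen, fwd$output, -batch$pair$a_d)
  cyc <- op_l1(xnode, back$output)
  total <- op_add(adv, op_smul(cyc, w$lambda_cc))
  ad_backward(total)
  opt_g <- adamw_step(g_params, opt_g, config$learning_rate,
                      config$weight_decay, config$betas[1], config$betas[2])
  list(opt = opt_g, generator_adv = adv$v, cycle = cyc$v,
       generator_total = total$v,
       map_range = range(fwd$mapping$v), out_range = range(fwd$output$v))
}

#' Train the conditional WGAN-GP
#'
#' Alternating optimization: the critic minimizes its Wasserstein core plus
#' the gradient penalty; after the scheduled number of critic updates the
#' generator minimizes its adversarial term plus the weighted
#' cycle-consistency loss on the critic's last source batch. Both networks
#' use decoupled-weight-decay Adam. The per-epoch loss history is returned
#' (and written as CSV when `out_dir` is given) and the checkpoint carries
#' the RNG state for exact resumption.
#'
#' @param config a [train_config()].
#' @param cohort a cohort table with a `train` split.
#' @param out_dir optional output directory for the history CSV, the run
#'   manifest and the per-epoch checkpoint.
#' @param resume optional checkpoint to resume from.
#' @param verbose print one line per epoch.
#' @return a `cardiosynth_model` (see [model_from_checkpoint()]).
#' @export
train_cgan <- function(config, cohort, out_dir = NULL, resume = NULL,
                       verbose = FALSE) {
  tr <- cohort[cohort$split == "train", ]
  attr(tr, "base_dir") <- attr(cohort, "base_dir")
  if (nrow(tr) == 0) stop("cohort has no train split")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_manifest(file.path(out_dir, "manifest.json"),
                   config = unclass(config), seed = config$seed,
                   cohort_csv = file.path(attr(cohort, "base_dir"),
                                          "cohort.csv"),
                   outputs = file.path(out_dir, c("history.csv",
                                                  "checkpoint.rds")))
  }
  imgs <- load_training_images(tr, config)
  if (is.null(resume)) {
    gen <- generator_net(config$net, seed = config$seed)
    critic <- critic_net(config$net, seed = config$seed + 1L)
    g_params <- params_of(gen); c_params <- params_of(critic)
    opt_g <- adamw_init(g_params); opt_c <- adamw_init(c_params)
    history <- NULL
    start_epoch <- 0L
    set.seed(derive_seed(config$seed, "training_stream"))
  } else {
    if (is.character(resume)) resume <- load_checkpoint(resume)
    nets <- restore_networks(resume)
    gen <- nets$gen; critic <- nets$critic
    g_params <- params_of(gen); c_params <- params_of(critic)
    opt_g <- adamw_init(g_params); opt_c <- adamw_init(c_params)
    for (i in seq_along(g_params)) {
      g_params[[i]]$m <- resume$gen_adam[[i]]$m
      g_params[[i]]$v2 <- resume$gen_adam[[i]]$v2
    }
    for (i in seq_along(c_params)) {
      c_params[[i]]$m <- resume$critic_adam[[i]]$m
      c_params[[i]]$v2 <- resume$critic_adam[[i]]$v2
    }
    opt_g$t <- unname(resume$opt_t["g"]); opt_c$t <- unname(resume$opt_t["c"])
    history <- resume$history
    start_epoch <- resume$epoch + 1L
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }
  ema_decay <- if (is.null(config$ema_decay)) 0 else config$ema_decay
  ema_values <- if (!is.null(resume) && !is.null(resume$gen_ema_values))
    resume$gen_ema_values
  else if (ema_decay > 0) lapply(g_params, function(p) p$v)
  else NULL
  steps_per_epoch <- max(1L, nrow(tr) %/% config$batch_size)
  pending_critic <- if (!is.null(resume) && !is.null(resume$pending_critic))
    resume$pending_critic else 0L
  last_batch <- NULL
  ckpt <- NULL
  for (epoch in start_epoch:(config$epochs - 1L)) {
    k <- critic_schedule(epoch, config$warmup_epochs,
                         config$critic_updates_warmup,
                         config$critic_updates_main)
    acc <- list(critic_core = 0, gp = 0, critic_total = 0, generator_adv = 0,
                cycle = 0, generator_total = 0)
    n_c <- 0L; n_g <- 0L
    for (step in seq_len(steps_per_epoch)) {
      batch <- draw_training_pair(tr, imgs, config$batch_size, config$gap_min,
                                  config$gap_max, config$age_range)
      batch$x <- augment_batch(batch$x, config$augment)
      batch$x_real <- augment_batch(batch$x_real, config$augment)
      cu <- critic_update(gen, critic, c_params, opt_c, batch, config)
      opt_c <- cu$opt
      n_c <- n_c + 1L
      pending_critic <- pending_critic + 1L
      acc$critic_core <- acc$critic_core + cu$critic_core
      acc$gp <- acc$gp + cu$gp
      acc$critic_total <- acc$critic_total + cu$critic_total
      last_batch <- batch
      if (pending_critic >= k) {
        gu <- generator_update(gen, critic, g_params, opt_g, last_batch,
                               config)
        opt_g <- gu$opt
        if (!is.null(ema_values))
          for (i in seq_along(g_params))
            ema_values[[i]] <- ema_decay * ema_values[[i]] +
              (1 - ema_decay) * g_params[[i]]$v
        n_g <- n_g + 1L
        pending_critic <- 0L
        acc$generator_adv <- acc$generator_adv + gu$generator_adv
        acc$cycle <- acc$cycle + gu$cycle
        acc$generator_total <- acc$generator_total + gu$generator_total
        if (gu$map_range[1] < -1 - 1e-9 || gu$map_range[2] > 1 + 1e-9 ||
            gu$out_range[1] < -1e-9 || gu$out_range[2] > 1 + 1e-9)
          stop("bound invariant violated during training")
      }
    }
    rec <- data.frame(
      epoch = epoch,
      critic_core = acc$critic_core / max(1, n_c),
      gp = acc$gp / max(1, n_c),
      critic_total = acc$critic_total / max(1, n_c),
      generator_adv = if (n_g) acc$generator_adv / n_g else NA_real_,
      cycle = if (n_g) acc$cycle / n_g else NA_real_,
      generator_total = if (n_g) acc$generator_total / n_g else NA_real_,
      n_critic_updates = n_c, n_generator_updates = n_g,
      schedule = k)
    if (!all(is.finite(unlist(rec[, 2:4])))) {
      if (!is.null(ckpt) && !is.null(out_dir))
        save_checkpoint(ckpt, file.path(out_dir, "checkpoint.rds"))
      stop(sprintf("non-finite loss at epoch %d; last good checkpoint %s",
                   epoch, if (is.null(ckpt)) "unavailable" else "saved"))
    }
    history <- rbind(history, rec)
    ckpt <- checkpoint_state(gen, critic, opt_g, opt_c, config, epoch, history,
                             ema_values, pending_critic)
    if (!is.null(out_dir)) {
      write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
      save_checkpoint(ckpt, file.path(out_dir, "checkpoint.rds"))
    }
    if (verbose)
      message(sprintf(paste0("epoch %3d  critic %8.4f  gp %7.4f  gen %8.4f  ",
                             "cycle %7.4f  (%d:%d)"),
                      epoch, rec$critic_core, rec$gp,
                      ifelse(is.na(rec$generator_adv), 0, rec$generator_adv),
                      ifelse(is.na(rec$cycle), 0, rec$cycle), n_c, n_g))
  }
  gen_ema <- NULL
  if (!is.null(ema_values)) {
    gen_ema <- generator_net(config$net, seed = config$seed)
    ge <- params_of(gen_ema)
    for (i in seq_along(ge)) ge[[i]]$v <- ema_values[[i]]
  }
  structure(list(generator = if (!is.null(gen_ema)) gen_ema else gen,
                 generator_raw = gen, critic = critic, config = config,
                 history = history, checkpoint = ckpt),
            class = "cardiosynth_model")
}

#' @export
print.cardiosynth_model <- function(x, ...) {
  cat(sprintf("cardiosynth_model: %d epochs trained, image size %d\n",
              nrow(x$history), x$config$target_size))
  invisible(x)
}
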