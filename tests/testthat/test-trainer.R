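test_that("preprocessing crops, resizes and rescales as specified", {
  img <- matrix(runif(210 * 218, 0, 255), 210, 218)
  out <- preprocess(img, crop_pixels_x = 90, target_size = 128)
  expect_equal(dim(out), c(128, 128))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  # odd crop favours the left; columns removed symmetrically otherwise
  img2 <- matrix(seq_len(10 * 100), 10, 100)
  cropped <- preprocess(img2, crop_pixels_x = 91, target_size = 10)
  expect_equal(dim(cropped), c(10, 10))
  expect_error(preprocess(matrix(0, 50, 80), crop_pixels_x = 90), "width")
  # constant image maps to zeros without division by zero
  expect_equal(preprocess(matrix(3, 100, 140), 90, 32), matrix(0, 32, 32))
})

test_that("augmentation keeps bounds, determinism, and monotone remaps", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  for (s in 1:20) {
    out <- augment(img, s)
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
    expect_identical(out, augment(img, s))
  }
  # identity path exists: some seed draws all three transforms as skipped
  idseeds <- vapply(1:200, function(s) identical(augment(img, s), img),
                    logical(1))
  expect_true(any(idseeds))
  # histogram remap preserves pixel rank order (monotone by construction):
  # compare rank orders on seeds where the spatially varying bias field was
  # skipped but the image changed
  rank_ok <- 0L
  for (s in 1:200) {
    out <- with_seed_probe <- augment(img, s)
    if (identical(out, img)) next
    if (all(rank(out) == rank(img))) rank_ok <- rank_ok + 1L
  }
  expect_gt(rank_ok, 10)
})

test_that("critic schedule follows the warm-up protocol", {
  expect_equal(critic_schedule(0), 50L)
  expect_equal(critic_schedule(19), 50L)
  expect_equal(critic_schedule(20), 5L)
  expect_equal(critic_schedule(250), 5L)
  expect_error(critic_schedule(-1), "non-negative")
})

test_that("training pairs respect truncation and the uniform gap law", {
  co <- data.frame(subject_id = sprintf("S%03d", 1:50),
                   age = rep(c(45, 64), c(25, 25)), bmi = 25, sex = "F",
                   phase = "ED", image_path = "x", mask_path = "x",
                   split = "train")
  imgs <- array(runif(8 * 8 * 50), c(8, 8, 50))
  p <- sample_training_pair(co, list(min = -25, max = 25), rng_seed = 4,
                            batch_size = 400, images = imgs)
  expect_true(all(p$pair$a_t >= 45 & p$pair$a_t <= 82))
  expect_equal(p$pair$a_d, p$pair$a_t - p$pair$a_s)
  # subjects at the lower boundary only receive non-negative gaps
  expect_true(all(p$pair$a_d[p$pair$a_s == 45] >= 0))
  # empirical mean gap near 0 for centered sources
  co64 <- co; co64$age <- rep(64, 50)
  p64 <- sample_training_pair(co64, list(min = -18, max = 18), rng_seed = 9,
                              batch_size = 10000, images = imgs)
  expect_lt(abs(mean(p64$pair$a_d)), 1)
  # reproducible given the seed
  q <- sample_training_pair(co, list(min = -25, max = 25), rng_seed = 4,
                            batch_size = 400, images = imgs)
  expect_identical(q$pair$a_t, p$pair$a_t)
  expect_error(sample_training_pair(co[0, ], rng_seed = 1), "empty")
})

toy_train_config <- function(n_epochs, seed, batch_size = 4L,
                             warmup_epochs = 0L, updates_warmup = 50L) {
  train_config(epochs = n_epochs, batch_size = batch_size,
               warmup_epochs = warmup_epochs,
               critic_updates_warmup = updates_warmup,
               critic_updates_main = 3L, learning_rate = 3e-4,
               crop_pixels_x = 0L, target_size = 16L, net = tiny_cfg(16),
               augment = FALSE, seed = seed)
}

test_that("a short training run produces a finite history and a resumable checkpoint", {
  co <- fixture_cohort(n = 30, size = 32, seed = 13)
  cfg2 <- toy_train_config(2L, seed = 21)
  m2 <- train_cgan(cfg2, co)
  expect_equal(nrow(m2$history), 2)
  expect_true(all(is.finite(unlist(m2$history[, c("critic_core", "gp",
                                                  "critic_total")]))))
  expect_true(all(is.finite(na.omit(unlist(m2$history[, c("generator_adv",
                                                          "cycle")])))))
  # resume after epoch 1 reproduces the uninterrupted trajectory exactly
  cfg1 <- toy_train_config(1L, seed = 21)
  m1 <- train_cgan(cfg1, co)
  ck <- m1$checkpoint
  ck$config <- cfg2
  m2b <- train_cgan(cfg2, co, resume = ck)
  expect_equal(m2b$history, m2$history, tolerance = 1e-12)
  v_a <- lapply(ns$params_of(m2$generator), function(p) p$v)
  v_b <- lapply(ns$params_of(m2b$generator), function(p) p$v)
  expect_equal(v_a, v_b, tolerance = 1e-12)
})

test_that("training reproduces identical loss histories under one seed", {
  co <- fixture_cohort(n = 30, size = 32, seed = 13)
  cfg <- toy_train_config(1L, seed = 33)
  h1 <- train_cgan(cfg, co)$history
  h2 <- train_cgan(cfg, co)$history
  expect_identical(h1, h2)
})

test_that("a warm-up epoch runs the scheduled critic:generator ratio", {
  co <- fixture_cohort(n = 30, size = 32, seed = 13)
  # 50 steps per epoch via batch size 1 on 30 training rows is too few, so
  # check the ratio bookkeeping directly: warm-up epoch with k = 10 on 20
  # steps must record exactly 2 generator updates
  cfg <- toy_train_config(1L, seed = 5, batch_size = 1L, warmup_epochs = 1L,
                          updates_warmup = 10L)
  m <- train_cgan(cfg, co)
  expect_equal(m$history$schedule, 10L)
  expect_equal(m$history$n_generator_updates,
               m$history$n_critic_updates %/% 10L)
})

test_that("checkpoints survive a save/load round trip", {
  co <- fixture_cohort(n = 30, size = 32, seed = 13)
  m <- train_cgan(toy_train_config(1L, seed = 2), co)
  p <- file.path(tempdir(), "ck.rds")
  save_checkpoint(m$checkpoint, p)
  model <- model_from_checkpoint(p)
  x <- matrix(runif(256), 16, 16)
  expect_identical(generator_forward(model$generator, x, 10)$output,
                   generator_forward(m$generator, x, 10)$output)
})
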