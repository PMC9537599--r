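test_that("Frechet distance matches closed forms and a brute-force oracle", {
  # identical statistics
  s <- feature_stats(c(1, 2), matrix(c(2, 0.5, 0.5, 1), 2))
  expect_lt(fid(s, s), 1e-10)
  # equal covariances: distance is the squared mean shift
  s2 <- feature_stats(c(3, -1), matrix(c(2, 0.5, 0.5, 1), 2))
  expect_equal(fid(s, s2), sum((c(1, 2) - c(3, -1))^2), tolerance = 1e-9)
  # 1-D closed form: (mu1 - mu2)^2 + (sd1 - sd2)^2
  a <- feature_stats(0, matrix(1))
  b <- feature_stats(1, matrix(4))
  expect_equal(fid(a, b), 1 + (1 - 2)^2, tolerance = 1e-12)
  # 100 random scalar-Gaussian pairs against the closed form
  set.seed(2)
  for (i in 1:100) {
    m1 <- rnorm(1); m2 <- rnorm(1); v1 <- runif(1, 0.1, 3); v2 <- runif(1, 0.1, 3)
    expect_equal(fid(feature_stats(m1, matrix(v1)), feature_stats(m2, matrix(v2))),
                 (m1 - m2)^2 + (sqrt(v1) - sqrt(v2))^2, tolerance = 1e-8)
  }
  # multivariate: brute-force oracle via eigendecomposition of sigma_a sigma_b
  set.seed(3)
  for (p in c(2, 4, 8)) {
    A <- crossprod(matrix(rnorm(p * p), p)) + diag(p) * 0.1
    B <- crossprod(matrix(rnorm(p * p), p)) + diag(p) * 0.1
    ma <- rnorm(p); mb <- rnorm(p)
    ev <- eigen(A %*% B)                       # non-symmetric route
    sq <- Re(ev$vectors %*% diag(sqrt(as.complex(ev$values))) %*%
               solve(ev$vectors))
    oracle <- sum((ma - mb)^2) + sum(diag(A)) + sum(diag(B)) -
      2 * sum(diag(sq))
    val <- fid(feature_stats(ma, A), feature_stats(mb, B))
    expect_equal(val, oracle, tolerance = 1e-6)
    # symmetry and non-negativity
    expect_equal(val, fid(feature_stats(mb, B), feature_stats(ma, A)),
                 tolerance = 1e-8)
    expect_gte(val, 0)
  }
  expect_error(fid(a, s), "dimension")
  expect_error(feature_stats(c(0, 0), matrix(c(1, 2, 2, -3), 2)),
               "positive semidefinite")
})

test_that("PSNR follows its definition and decreases with noise", {
  x <- matrix(runif(64), 8, 8)
  expect_equal(psnr(x, x), Inf)
  y <- x; y[1] <- y[1] + 0.8
  expect_equal(psnr(x, y), 10 * log10(1 / mean((x - y)^2)))
  # exact values from fixed MSE
  a <- matrix(0, 10, 10); b <- a; b[] <- 0.1
  expect_equal(psnr(a, b), 20)                 # MSE 0.01 -> 20 dB
  expect_equal(psnr(a, a + 1), 0)              # MSE 1 -> 0 dB
  expect_error(psnr(a, matrix(0, 5, 5)), "shape")
  set.seed(1)
  img <- render_phantom(geometry_from_covariates(60, jitter = FALSE,
                                                 image_size = 64),
                        noise_sd = 0)$image
  vals <- vapply(c(0.01, 0.03, 0.1, 0.3), function(s)
    psnr(img, pmin(pmax(img + rnorm(length(img), 0, s), 0), 1)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("volumetric metrics recover phantom geometry and compute EF", {
  g <- geometry_from_covariates(58, jitter = FALSE, image_size = 96)
  s <- render_phantom(g, noise_sd = 0)
  m <- volumetric_metrics(s$mask)
  expect_lt(abs(m$septum_width - g$septum_width), 1)
  # EF from a paired ES mask
  g_es <- geometry_from_covariates(58, jitter = FALSE, image_size = 96,
                                   phase = "ES")
  s_es <- render_phantom(g_es, noise_sd = 0)
  m2 <- volumetric_metrics(s$mask, s_es$mask)
  expect_gt(m2$ejection_fraction, 0.3)
  expect_lt(m2$ejection_fraction, 0.7)
  # trivial EF identities on synthetic masks
  mk <- s$mask
  expect_equal(volumetric_metrics(mk, mk)$ejection_fraction, 0)
  half <- mk
  lvpix <- which(half == 1L)
  half[lvpix[seq(1, length(lvpix), 2)]] <- 2L   # reassign half the LV pixels
  ef <- volumetric_metrics(mk, half)$ejection_fraction
  expect_equal(ef, 0.5, tolerance = 0.01)
  # missing labels are reported by name
  expect_error(volumetric_metrics(matrix(0L, 8, 8)), "label 1")
})

test_that("normalized variation is centered on the original population", {
  orig <- c(10, 12, 8, 10)
  expect_equal(normalized_variation(10, orig), 0)
  expect_equal(normalized_variation(10.5, orig), 0.05)
  expect_equal(mean(normalized_variation(orig, orig)), 0)
  expect_error(normalized_variation(1, numeric(0)), "empty")
  expect_error(normalized_variation(1, c(-1, 1)), "zero")
})

test_that("rule-based segmentation matches rendered masks", {
  set.seed(9)
  agree <- vapply(1:20, function(i) {
    g <- geometry_from_covariates(runif(1, 45, 82), bmi = runif(1, 20, 32),
                                  rng_seed = i)
    s <- render_phantom(g, noise_sd = 0)
    mean(segment_generated(s$image) == s$mask)
  }, numeric(1))
  expect_true(all(agree >= 0.98))
  expect_error(segment_generated(matrix(0, 32, 32)), "no region")
  # deterministic
  s <- render_phantom(geometry_from_covariates(66, rng_seed = 2),
                      noise_sd = 0.02, rng_seed = 2)
  expect_identical(segment_generated(s$image), segment_generated(s$image))
})

test_that("feature extraction is deterministic with PSD shrinkage", {
  co <- fixture_cohort(n = 40, size = 32, seed = 7)
  imgs <- load_cohort_images(co)
  ex <- train_feature_extractor(co, imgs, epochs = 1L, seed = 3)
  f1 <- extract_features(imgs[, , 1:20], ex)
  f2 <- extract_features(imgs[, , 1:20], ex)
  expect_equal(f1$mu, f2$mu)
  # duplicated set against itself: FID 0
  expect_lt(fid(f1, f2), 1e-10)
  # shrinkage path: n <= dim still yields PSD covariance
  fs <- extract_features(imgs[, , 1:10], ex)       # 10 images, 32-dim features
  ev <- eigen(fs$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_error(extract_features(imgs[, , 1, drop = FALSE], ex), "at least 2")
})

test_that("predicted-covariate MAE bookkeeping matches a perfect regressor", {
  # images encode their covariate as a constant intensity = age / 100,
  # so the oracle regressor is exact and the zero-order error is |gap|
  ages <- c(50, 55, 60, 65, 70)
  imgs <- array(rep(ages / 100, each = 16 * 16), c(16, 16, length(ages)))
  reg <- oracle_regressor()
  gen_id <- identity_generator(tiny_cfg(16))
  tab <- predicted_covariate_mae(reg, gen_id, imgs, ages, gaps = c(-5, 0, 5))
  z <- tab[tab$method == "zero_order", ]
  expect_equal(z$mae, abs(z$gap))
  # identity generator scored by the perfect regressor also errs by |gap|
  m <- tab[tab$method == "model", ]
  expect_equal(m$mae, abs(m$gap))
  # gap 0 with identity generator and perfect regressor: zero error
  expect_equal(tab$mae[tab$gap == 0], c(0, 0))
  # out-of-range targets are dropped
  tab2 <- predicted_covariate_mae(reg, gen_id, imgs, ages, gaps = 20)
  expect_equal(tab2$n[1], sum(ages + 20 <= 82))
  expect_error(predicted_covariate_mae(reg, gen_id,
                                       array(0, c(16, 16, 0)), numeric(0), 5),
               "empty")
})

test_that("shuffled labels drive the regressor to the null-model error", {
  co <- fixture_cohort(n = 60, size = 32, seed = 19)
  imgs <- load_cohort_images(co)
  co_shuf <- co
  set.seed(4)
  co_shuf$age <- sample(co_shuf$age)
  reg <- train_covariate_regressor(co_shuf, imgs, epochs = 4L, seed = 2)
  null_mae <- mean(abs(co$age[co$split == "val"] -
                         mean(co$age[co$split == "train"])))
  expect_lt(abs(reg$holdout_mae - null_mae), 0.6 * null_mae)
  expect_error(train_covariate_regressor(within(co, age <- 60), imgs),
               "degenerate")
})
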