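test_that("imbalanced dataset construction hits exact counts", {
  ages <- c(runif(300, 45, 69.9), runif(120, 70.1, 82))
  co <- data.frame(subject_id = sprintf("S%04d", seq_along(ages)), age = ages,
                   bmi = 25, sex = "F", phase = "ED", image_path = "x",
                   mask_path = "x", split = "train")
  sp <- imbalance_spec(n_total = 200, threshold = 70, minority_side = "older",
                       minority_fraction = 0.1)
  d <- build_imbalanced_dataset(co, sp, seed = 3)
  expect_equal(nrow(d), 200)
  expect_equal(sum(d$age < 70), 180)
  expect_equal(sum(d$age >= 70), 20)
  # property: exact counts across random specs
  set.seed(8)
  for (i in 1:10) {
    n <- sample(50:220, 1)
    mf <- runif(1, 0.05, 0.45)
    sideval <- sample(c("older", "younger"), 1)
    spi <- imbalance_spec(n, 70, sideval, mf)
    di <- tryCatch(build_imbalanced_dataset(co, spi, seed = i),
                   error = function(e) NULL)
    if (is.null(di)) next
    n_min <- round(n * mf)
    got_min <- if (sideval == "older") sum(di$age >= 70) else sum(di$age < 70)
    expect_equal(got_min, n_min)
  }
  # determinism and failure mode
  expect_identical(build_imbalanced_dataset(co, sp, seed = 5)$subject_id,
                   build_imbalanced_dataset(co, sp, seed = 5)$subject_id)
  expect_error(build_imbalanced_dataset(co, imbalance_spec(2000, 70), 1),
               "cannot satisfy")
})

test_that("D2-style specs invert the imbalance", {
  ages <- c(runif(150, 45, 59.9), runif(300, 60.1, 82))
  co <- data.frame(subject_id = sprintf("S%04d", seq_along(ages)), age = ages,
                   bmi = 25, sex = "F", phase = "ED", image_path = "x",
                   mask_path = "x", split = "train")
  sp <- imbalance_spec(n_total = 200, threshold = 60,
                       minority_side = "younger", minority_fraction = 0.1)
  d <- build_imbalanced_dataset(co, sp, seed = 1)
  expect_equal(sum(d$age > 60), 180)
})

test_that("synthetic augmentation adds flagged rows inside the minority region", {
  co <- fixture_cohort(n = 40, size = 32, seed = 23)
  sp <- imbalance_spec(n_total = 20, threshold = 65, minority_side = "older",
                       minority_fraction = 0.2)
  ds <- build_imbalanced_dataset(co, sp, seed = 2)
  gen <- identity_generator(tiny_cfg(16))
  expect_warning(unchanged <- augment_with_synthetic(ds, gen, 0, sp),
                 "unchanged")
  expect_equal(nrow(unchanged), nrow(ds))
  aug <- augment_with_synthetic(ds, gen, 0.10, sp, seed = 4)
  added <- aug[aug$synthetic == 1L, ]
  expect_equal(nrow(added), round(0.10 * nrow(ds)))
  expect_true(all(added$age >= 65 & added$age <= 82))
  # synthetic images were written and are readable
  imgs <- load_cohort_images(added)
  expect_true(all(imgs >= 0 & imgs <= 1))
})

test_that("alternative task configurations expose the documented settings", {
  bmi <- configure_alternative_task("bmi")
  expect_equal(bmi$eval_gaps, c(-8, -6, -4, -2, -1, 0, 1, 2, 4, 6, 8))
  expect_equal(bmi$gap_max, 8)
  ph <- configure_alternative_task("phase")
  expect_equal(ph$eval_gaps, c(-1, 0, 1))
  expect_true(ph$paired_rmse)
  age <- configure_alternative_task("age")
  expect_equal(age$covariate_mode, "age")
  expect_error(configure_alternative_task("height"))
})

test_that("zero-order BMI analogue errs by the gap under a perfect regressor", {
  bmis <- c(22, 24, 26, 28, 30)
  imgs <- array(rep(bmis / 100, each = 16 * 16), c(16, 16, length(bmis)))
  tab <- predicted_covariate_mae(oracle_regressor(),
                                 identity_generator(tiny_cfg(16)), imgs, bmis,
                                 gaps = c(-4, -2, 2, 4), age_range = c(18, 38))
  z <- tab[tab$method == "zero_order", ]
  expect_equal(z$mae, abs(z$gap))
})
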