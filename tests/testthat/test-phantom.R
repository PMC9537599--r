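test_that("geometry law evaluates linearly in age", {
  sl <- phantom_slopes()
  sl$septum0 <- 4; sl$septum_slope <- 0.1
  g <- geometry_from_covariates(65, slopes = sl, jitter = FALSE)
  expect_equal(g$septum_width, 4 + 0.1 * 20)
  sl2 <- phantom_slopes()
  sl2$lv0 <- 22; sl2$lv_slope <- 0.15
  g2 <- geometry_from_covariates(45, slopes = sl2, jitter = FALSE)
  expect_equal(g2$lv_cavity_radius, 22)
})

test_that("geometry is deterministic and validates its inputs", {
  a <- geometry_from_covariates(60.5, bmi = 27, rng_seed = 99)
  b <- geometry_from_covariates(60.5, bmi = 27, rng_seed = 99)
  expect_identical(a, b)
  expect_error(geometry_from_covariates(40), "outside")
  expect_error(geometry_from_covariates(90), "outside")
})

test_that("morphology is monotone in age on a yearly grid (jitter off)", {
  gs <- lapply(45:82, geometry_from_covariates, jitter = FALSE)
  septum <- sapply(gs, `[[`, "septum_width")
  lv <- sapply(gs, `[[`, "lv_cavity_radius")
  aorta <- sapply(gs, `[[`, "aorta_radius")
  expect_true(all(diff(septum) > 0))
  expect_true(all(diff(aorta) > 0))
  expect_true(all(diff(lv) < 0))
  expect_true(all(septum < lv))
})

test_that("noiseless rendering hits the configured tissue intensities", {
  g <- geometry_from_covariates(60, jitter = FALSE, image_size = 64)
  s <- render_phantom(g, noise_sd = 0)
  ti <- g$tissue_intensities
  # LV cavity interior (eroded by 1 px) is exactly the LV intensity
  lv <- s$mask == 1L
  core <- lv & EBImage::erode(lv, EBImage::makeBrush(3, "box")) > 0
  expect_true(all(abs(s$image[core] - ti[["lv"]]) < 1e-12))
  expect_gte(min(s$image), 0)
  expect_lte(max(s$image), 1)
  # every labelled region nonempty, intensities match within noise tolerance
  s2 <- render_phantom(g, noise_sd = 0.02, rng_seed = 3)
  brush <- EBImage::makeBrush(3, "box")
  for (lab in c(lv = 1L, myo = 2L, rv = 3L, la = 4L, ra = 5L, aorta = 6L)) {
    px <- s2$mask == lab
    expect_gt(sum(px), 0)
    # interior only: boundary pixels are anti-aliased mixtures by design
    core <- EBImage::erode(px, brush) > 0
    if (sum(core) < 4) next
    nm <- names(ns$phantom_labels)[ns$phantom_labels == lab]
    expect_lt(abs(mean(s2$image[core]) - ti[[nm]]),
              3 * 0.02 / sqrt(sum(core)) + 0.005)
  }
})

test_that("rendered septum width recovers the parameter within 1 px", {
  set.seed(31)
  for (i in 1:10) {
    age <- runif(1, 45, 82)
    g <- geometry_from_covariates(age, rng_seed = i, jitter = TRUE)
    s <- render_phantom(g, noise_sd = 0)
    # oracle: count myocardium pixels along scanlines between the cavities
    m <- volumetric_metrics(s$mask)
    expect_lt(abs(m$septum_width - g$septum_width), 1)
    expect_lt(abs(m$lv_area - pi * g$lv_cavity_radius^2),
              0.05 * pi * g$lv_cavity_radius^2)
  }
})

test_that("rendering is deterministic and clips noisy intensities", {
  g <- geometry_from_covariates(70, rng_seed = 2)
  s1 <- render_phantom(g, noise_sd = 0.4, rng_seed = 5)
  s2 <- render_phantom(g, noise_sd = 0.4, rng_seed = 5)
  expect_identical(s1$image, s2$image)
  expect_gte(min(s1$image), 0)
  expect_lte(max(s1$image), 1)
})

test_that("geometry violating the frame or the septum bound errors", {
  g <- geometry_from_covariates(60, jitter = FALSE)
  g$aorta_radius <- 60
  expect_error(ns$validate_geometry(g), "aorta")
  g2 <- geometry_from_covariates(60, jitter = FALSE)
  g2$septum_width <- g2$lv_cavity_radius + 1
  expect_error(ns$validate_geometry(g2), "septum")
})

test_that("cohort generation writes a consistent, reproducible table", {
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  c1 <- generate_cohort(10, d1, image_size = 32, age_distribution = "uniform",
                        rng_seed = 3)
  c2 <- generate_cohort(10, d2, image_size = 32, age_distribution = "uniform",
                        rng_seed = 3)
  expect_equal(length(unique(c1$subject_id)), 10)
  expect_true(all(c1$age >= 45 & c1$age <= 82))
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  # files exist and round-trip through the reader
  imgs <- load_cohort_images(c1)
  expect_equal(dim(imgs), c(32, 32, 10))
  expect_true(all(imgs >= 0 & imgs <= 1))
  rt <- read_cohort(file.path(d1, "cohort.csv"))
  expect_equal(rt$age, c1$age)
})

test_that("truncated-normal ages have the configured moments", {
  co <- generate_cohort(2000, file.path(tempdir(), "coh_tn"), image_size = 32,
                        noise_sd = 0, jitter = FALSE, rng_seed = 12)
  expect_lt(abs(mean(co$age) - 64.1), 3 * 7.7 / sqrt(2000))
  expect_true(all(co$age >= 45 & co$age <= 82))
})

test_that("phase mode emits paired ED/ES samples with contracted cavities", {
  co <- fixture_cohort(n = 6, size = 48, mode = "phase", seed = 4)
  expect_equal(nrow(co), 12)
  expect_setequal(unique(co$phase), c("ED", "ES"))
  masks <- load_cohort_images(co, "mask")
  for (sid in unique(co$subject_id)) {
    ed <- which(co$subject_id == sid & co$phase == "ED")
    es <- which(co$subject_id == sid & co$phase == "ES")
    expect_gt(sum(masks[, , ed] == 1), sum(masks[, , es] == 1))
  }
})
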