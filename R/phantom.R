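# Synthetic four-chamber cardiac phantom.
#
# A deterministic geometric law maps scalar covariates to morphology: with
# age, the interventricular septum thickens, the LV cavity shrinks and the
# aorta dilates (all linear in age, with optional per-subject Gaussian
# jitter); BMI controls the width of a peripheral fat band; the ES phase
# contracts both cavities and thickens the myocardium. Because the law is
# known exactly, generative models trained on phantom cohorts can be tested
# for parameter recovery.
#
# Coordinates are row-major with the origin at the top-left corner and
# 0-based pixel centers. All geometry defaults are expressed at a reference
# side length of 128 pixels and scale linearly with image size.

phantom_labels <- c(bg = 0L, lv = 1L, myo = 2L, rv = 3L, la = 4L, ra = 5L,
                    aorta = 6L)

phantom_intensities <- function() {
  c(bg = 0.05, lv = 0.90, myo = 0.40, rv = 0.78, la = 0.66, ra = 0.55,
    aorta = 0.98, fat = 0.95)
}

#' Default covariate-to-geometry slopes of the phantom (reference size 128)
#'
#' Linear laws, anchored at age 45: septum width `s0 + s1 (age - 45)`,
#' LV cavity radius `r0 - r1 (age - 45)`, aorta radius `rho0 + rho1 (age - 45)`.
#' The slopes move each structure by about 2-4 pixels per 20 years at a side
#' length of 128.
#'
#' @return named list of intercepts, slopes and jitter standard deviations
#'   (pixels at reference size 128, per-year slopes).
#' @export
phantom_slopes <- function() {
  list(septum0 = 5, septum_slope = 0.15,
       lv0 = 24, lv_slope = 0.15,
       aorta0 = 6, aorta_slope = 0.1,
       rv_thickness = 9, la_radius = 9, ra_radius = 8.5,
       fat_per_bmi = 0.3, fat_bmi_anchor = 22,
       es_lv_scale = 0.70, es_rv_scale = 0.72, es_septum_scale = 1.25,
       jitter = c(lv = 0.5, septum = 0.15, rv = 0.4, la = 0.3, ra = 0.3,
                  aorta = 0.2, center = 1.0, rotation = 3.0))
}

#' Phantom geometry from covariates
#'
#' Evaluates the deterministic covariate-to-morphology law and (optionally)
#' adds per-subject Gaussian jitter. Deterministic given
#' `(age, bmi, sex, phase, rng_seed)`.
#'
#' @param age age in years, inside `age_range`.
#' @param bmi body mass index in kg/m2 (controls the peripheral fat band).
#' @param sex `"F"` or `"M"` (metadata only by default).
#' @param rng_seed integer seed for the jitter draws.
#' @param image_size target side length in pixels.
#' @param phase `"ED"` or `"ES"`.
#' @param slopes a [phantom_slopes()] list.
#' @param jitter logical; disable for exactly linear geometry.
#' @param age_range admissible age interval.
#' @return an object of class `geometry_params` with fields
#'   `lv_cavity_radius`, `septum_width`, `rv_radius`, `la_radius`,
#'   `ra_radius`, `aorta_radius`, `heart_center`, `rotation`,
#'   `fat_width` and `tissue_intensities`, all in pixels at `image_size`.
#' @export
geometry_from_covariates <- function(age, bmi = 26, sex = c("F", "M"),
                                     rng_seed = 1L, image_size = 128L,
                                     phase = c("ED", "ES"),
                                     slopes = phantom_slopes(), jitter = TRUE,
                                     age_range = c(45, 82)) {
  sex <- match.arg(sex)
  phase <- match.arg(phase)
  if (age < age_range[1] || age > age_range[2])
    stop(sprintf("age %.1f outside configured range [%g, %g]",
                 age, age_range[1], age_range[2]))
  k <- image_size / 128
  t <- age - age_range[1]
  base <- list(
    lv = (slopes$lv0 - slopes$lv_slope * t) * k,
    septum = (slopes$septum0 + slopes$septum_slope * t) * k,
    rv = slopes$rv_thickness * k,
    la = slopes$la_radius * k,
    ra = slopes$ra_radius * k,
    aorta = (slopes$aorta0 + slopes$aorta_slope * t) * k,
    center = c(0.44, 0.40) * image_size,
    rotation = 0)
  if (phase == "ES") {
    base$lv <- base$lv * slopes$es_lv_scale
    base$rv <- base$rv * slopes$es_rv_scale
    base$septum <- base$septum * slopes$es_septum_scale
  }
  fat <- max(0, (bmi - slopes$fat_bmi_anchor) * slopes$fat_per_bmi) * k
  jsd <- slopes$jitter
  make <- function(jit) {
    g <- list(
      lv_cavity_radius = base$lv + jit[["lv"]],
      septum_width = base$septum + jit[["septum"]],
      rv_radius = base$rv + jit[["rv"]],
      la_radius = base$la + jit[["la"]],
      ra_radius = base$ra + jit[["ra"]],
      aorta_radius = base$aorta + jit[["aorta"]],
      heart_center = unname(base$center) + c(jit[["crow"]], jit[["ccol"]]),
      rotation = base$rotation + jit[["rotation"]],
      fat_width = fat,
      image_size = as.integer(image_size),
      age = age, bmi = bmi, sex = sex, phase = phase,
      tissue_intensities = phantom_intensities())
    names(g$heart_center) <- c("row", "col")
    structure(g, class = "geometry_params")
  }
  zero <- setNames(numeric(7), c("lv", "septum", "rv", "la", "ra", "aorta",
                                 "rotation"))
  if (!jitter) {
    jit <- c(zero, crow = 0, ccol = 0)
    return(validate_geometry(make(jit)))
  }
  with_seed(rng_seed, paste0("geometry_jitter_", age, "_", bmi, "_", phase), {
    for (attempt in 1:20) {
      jit <- c(lv = rnorm(1, 0, jsd["lv"] * k),
               septum = rnorm(1, 0, jsd["septum"] * k),
               rv = rnorm(1, 0, jsd["rv"] * k),
               la = rnorm(1, 0, jsd["la"] * k),
               ra = rnorm(1, 0, jsd["ra"] * k),
               aorta = rnorm(1, 0, jsd["aorta"] * k),
               rotation = rnorm(1, 0, jsd["rotation"]),
               crow = rnorm(1, 0, jsd["center"] * k),
               ccol = rnorm(1, 0, jsd["center"] * k))
      names(jit) <- c("lv", "septum", "rv", "la", "ra", "aorta", "rotation",
                      "crow", "ccol")
      g <- tryCatch(validate_geometry(make(jit)), error = function(e) NULL)
      if (!is.null(g)) return(g)
    }
    stop("could not draw admissible geometry jitter within the retry cap")
  })
}

# Centers of the auxiliary structures, derived from the heart center with the
# rotation applied to the offset vectors.
phantom_centers <- function(g) {
  S <- g$image_size
  th <- g$rotation * pi / 180
  rot <- function(off) {
    c(off[1] * cos(th) - off[2] * sin(th), off[1] * sin(th) + off[2] * cos(th))
  }
  list(lv = g$heart_center,
       la = g$heart_center + rot(c(0.27, 0.02) * S),
       ra = g$heart_center + rot(c(0.29, 0.24) * S),
       aorta = g$heart_center + rot(c(-0.28, 0.13) * S))
}

validate_geometry <- function(g) {
  vals <- c(g$lv_cavity_radius, g$septum_width, g$rv_radius, g$la_radius,
            g$ra_radius, g$aorta_radius)
  if (any(vals <= 0)) stop("all radii and widths must be positive")
  if (g$septum_width >= g$lv_cavity_radius)
    stop("septum_width must be smaller than lv_cavity_radius")
  S <- g$image_size
  ctr <- phantom_centers(g)
  ext <- c(
    lv = max(abs(ctr$lv - S / 2)) + g$lv_cavity_radius + g$septum_width +
      g$rv_radius,
    la = max(abs(ctr$la - S / 2)) + g$la_radius,
    ra = max(abs(ctr$ra - S / 2)) + g$ra_radius,
    aorta = max(abs(ctr$aorta - S / 2)) + g$aorta_radius)
  bad <- names(ext)[ext > S / 2 - 1]
  if (length(bad))
    stop(sprintf("structure(s) exceed the image frame: %s",
                 paste(bad, collapse = ", ")))
  g
}

#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf(paste0("geometry_params (size %d, age %.1f, %s): lv=%.2f ",
                     "septum=%.2f rv=%.2f aorta=%.2f rot=%.1f\n"),
              x$image_size, x$age, x$phase, x$lv_cavity_radius,
              x$septum_width, x$rv_radius, x$aorta_radius, x$rotation))
  invisible(x)
}

# Anti-aliased coverage of a disc, 3x3 supersampling; rr/cc are 0-based pixel
# center grids (matrices).
cov_disc <- function(rr, cc, cr, ccol, radius) {
  cov <- 0
  for (dr in c(-1, 0, 1) / 3) for (dc in c(-1, 0, 1) / 3) {
    cov <- cov + (((rr + dr - cr)^2 + (cc + dc - ccol)^2) <= radius^2)
  }
  cov / 9
}

# Coverage of an annular sector around (cr, ccol): radii in [r1, r2], angle
# within halfwidth of th0 (radians; 0 points toward increasing column).
cov_sector <- function(rr, cc, cr, ccol, r1, r2, th0, halfwidth) {
  cov <- 0
  for (dr in c(-1, 0, 1) / 3) for (dc in c(-1, 0, 1) / 3) {
    dy <- rr + dr - cr
    dx <- cc + dc - ccol
    d2 <- dx^2 + dy^2
    ang <- atan2(dy, dx) - th0
    ang <- atan2(sin(ang), cos(ang))            # wrap to (-pi, pi]
    cov <- cov + ((d2 >= r1^2) & (d2 <= r2^2) & (abs(ang) <= halfwidth))
  }
  cov / 9
}

#' Render a phantom image and label mask from geometry parameters
#'
#' Draws anti-aliased disc/annulus primitives back-to-front (aorta last) at
#' region-specific mean intensities, adds Gaussian pixel noise and clips to
#' `[0, 1]`. The mask is rendered without noise; a pixel carries a region's
#' label when the region covers more than half of it.
#'
#' @param params a [geometry_from_covariates()] result.
#' @param image_size side length (defaults to the size the geometry was
#'   generated for).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param rng_seed seed for the noise draw.
#' @return an object of class `phantom_sample`: list with `image` (matrix in
#'   `[0,1]`), `mask` (integer matrix, labels 0-6), the covariates and the
#'   geometry.
#' @export
render_phantom <- function(params, image_size = params$image_size,
                           noise_sd = 0.02, rng_seed = 1L) {
  stopifnot(inherits(params, "geometry_params"), image_size >= 32,
            noise_sd >= 0)
  if (image_size != params$image_size)
    stop("image_size differs from the size the geometry was generated for")
  validate_geometry(params)
  S <- image_size
  ti <- params$tissue_intensities
  rr <- matrix(0:(S - 1), S, S)
  cc <- matrix(0:(S - 1), S, S, byrow = TRUE)
  ctr <- phantom_centers(params)
  img <- matrix(ti["bg"], S, S)
  mask <- matrix(0L, S, S)
  paint <- function(cov, intensity, label) {
    img <<- img * (1 - cov) + intensity * cov
    if (label > 0L) mask[cov > 0.5] <<- label
    invisible(NULL)
  }
  if (params$fat_width > 0.5) {
    band <- (rr < params$fat_width) | (rr > S - 1 - params$fat_width) |
      (cc < params$fat_width) | (cc > S - 1 - params$fat_width)
    paint(band * 1, ti["fat"], 0L)
  }
  th0 <- params$rotation * pi / 180
  # myocardium disc (ring once LV is painted over it)
  paint(cov_disc(rr, cc, ctr$lv[1], ctr$lv[2],
                 params$lv_cavity_radius + params$septum_width),
        ti["myo"], phantom_labels["myo"])
  paint(cov_disc(rr, cc, ctr$lv[1], ctr$lv[2], params$lv_cavity_radius),
        ti["lv"], phantom_labels["lv"])
  paint(cov_sector(rr, cc, ctr$lv[1], ctr$lv[2],
                   params$lv_cavity_radius + params$septum_width,
                   params$lv_cavity_radius + params$septum_width +
                     params$rv_radius,
                   th0, 65 * pi / 180),
        ti["rv"], phantom_labels["rv"])
  paint(cov_disc(rr, cc, ctr$la[1], ctr$la[2], params$la_radius),
        ti["la"], phantom_labels["la"])
  paint(cov_disc(rr, cc, ctr$ra[1], ctr$ra[2], params$ra_radius),
        ti["ra"], phantom_labels["ra"])
  paint(cov_disc(rr, cc, ctr$aorta[1], ctr$aorta[2], params$aorta_radius),
        ti["aorta"], phantom_labels["aorta"])
  if (noise_sd > 0)
    img <- img + with_seed(rng_seed, "render_noise",
                           matrix(rnorm(S * S, 0, noise_sd), S, S))
  img <- pmin(pmax(img, 0), 1)
  for (lab in c("lv", "myo", "rv", "la", "ra", "aorta")) {
    rad <- switch(lab, lv = params$lv_cavity_radius,
                  myo = params$septum_width, rv = params$rv_radius,
                  la = params$la_radius, ra = params$ra_radius,
                  aorta = params$aorta_radius)
    if (rad > 1 && !any(mask == phantom_labels[lab]))
      stop(sprintf("region %s has radius > 1 px but rendered empty", lab))
  }
  structure(list(image = img, mask = mask, age = params$age,
                 bmi = params$bmi, sex = params$sex, phase = params$phase,
                 geometry = params, subject_id = NA_character_),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample %s: %dx%d, age %.1f, bmi %.1f, %s/%s\n",
              x$subject_id, nrow(x$image), ncol(x$image), x$age, x$bmi,
              x$sex, x$phase))
  invisible(x)
}

sample_ages <- function(n, distribution = c("truncnorm", "uniform"),
                        range = c(45, 82), mean = 64.1, sd = 7.7) {
  distribution <- match.arg(distribution)
  if (distribution == "uniform") return(runif(n, range[1], range[2]))
  lo <- pnorm((range[1] - mean) / sd)
  hi <- pnorm((range[2] - mean) / sd)
  qnorm(runif(n, lo, hi)) * sd + mean
}

#' Generate a phantom cohort on disk
#'
#' Draws covariates, evaluates the geometry law per subject, renders images
#' and masks, writes them under `out_dir` (16-bit grayscale PNG images, 8-bit
#' PNG label masks) and returns the cohort table. In `covariate_mode =
#' "phase"` each subject gets a paired ED and ES sample.
#'
#' @param n number of subjects (`n >= 1`).
#' @param out_dir output directory (created if missing).
#' @param image_size rendered side length.
#' @param age_distribution `"truncnorm"` (mean 64.1, sd 7.7, truncated to the
#'   age range) or `"uniform"`.
#' @param covariate_mode `"age"`, `"bmi"` or `"phase"`.
#' @param noise_sd pixel noise level.
#' @param jitter logical, per-subject geometry jitter.
#' @param rng_seed root seed.
#' @param splits named proportions for the train/val/test split tags.
#' @param age_range admissible ages.
#' @return a `data.frame` (class `cohort_table`) with columns `subject_id`,
#'   `age`, `bmi`, `sex`, `phase`, `image_path`, `mask_path`, `split`; paths
#'   are relative to `out_dir`, which is stored in the `base_dir` attribute.
#' @export
generate_cohort <- function(n, out_dir, image_size = 128L,
                            age_distribution = c("truncnorm", "uniform"),
                            covariate_mode = c("age", "bmi", "phase"),
                            noise_sd = 0.02, jitter = TRUE, rng_seed = 1L,
                            splits = c(train = 0.7, val = 0.15, test = 0.15),
                            age_range = c(45, 82)) {
  stopifnot(n >= 1)
  covariate_mode <- match.arg(covariate_mode)
  age_distribution <- match.arg(age_distribution)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create out_dir '%s'", out_dir))
  covs <- with_seed(rng_seed, "cohort_covariates", {
    ages <- sample_ages(n, age_distribution, age_range)
    bmis <- pmin(pmax(rnorm(n, 26.5, 4), 18), 38)
    sexes <- sample(c("F", "M"), n, replace = TRUE)
    u <- runif(n)
    cum <- cumsum(splits) / sum(splits)
    split <- names(splits)[findInterval(u, c(0, cum), rightmost.closed = TRUE)]
    list(ages = ages, bmis = bmis, sexes = sexes, split = split)
  })
  phases <- if (covariate_mode == "phase") c("ED", "ES") else "ED"
  rows <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("S%05d", i)
    for (ph in phases) {
      g <- geometry_from_covariates(covs$ages[i], covs$bmis[i], covs$sexes[i],
                                    rng_seed = derive_seed(rng_seed,
                                                           paste0("subj", i)),
                                    image_size = image_size, phase = ph,
                                    jitter = jitter, age_range = age_range)
      ps <- render_phantom(g, image_size, noise_sd,
                           rng_seed = derive_seed(rng_seed,
                                                  paste0("noise", i, ph)))
      img_rel <- sprintf("images/%s_%s.png", sid, ph)
      msk_rel <- sprintf("masks/%s_%s.png", sid, ph)
      dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
      dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
      write_image(ps$image, file.path(out_dir, img_rel))
      write_mask(ps$mask, file.path(out_dir, msk_rel))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, age = covs$ages[i], bmi = covs$bmis[i],
        sex = covs$sexes[i], phase = ph, image_path = img_rel,
        mask_path = msk_rel, split = covs$split[i],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  write_cohort(tab, file.path(out_dir, "cohort.csv"))
  attr(tab, "base_dir") <- out_dir
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write / read a cohort table
#'
#' @param cohort a cohort `data.frame`.
#' @param path CSV path.
#' @return `read_cohort` returns the table with its `base_dir` attribute set
#'   to the CSV's directory.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort)[, c("subject_id", "age", "bmi", "sex",
                                      "phase", "image_path", "mask_path",
                                      "split")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  attr(tab, "base_dir") <- dirname(path)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Load the images (or masks) referenced by a cohort table
#'
#' @param cohort a cohort table with a `base_dir` attribute.
#' @param what `"image"` or `"mask"`.
#' @return array `(H, W, N)` of intensities, or integer array of labels.
#' @export
load_cohort_images <- function(cohort, what = c("image", "mask")) {
  what <- match.arg(what)
  base <- attr(cohort, "base_dir")
  col <- if (what == "image") "image_path" else "mask_path"
  paths <- file.path(base, cohort[[col]])
  first <- if (what == "image") read_image(paths[1]) else read_mask(paths[1])
  out <- array(if (what == "image") 0 else 0L,
               c(nrow(first), ncol(first), length(paths)))
  out[, , 1] <- first
  if (length(paths) > 1)
    for (i in 2:length(paths))
      out[, , i] <- if (what == "image") read_image(paths[i])
                    else read_mask(paths[i])
  out
}
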