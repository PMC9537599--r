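# Quantitative evaluation protocol: predicted-covariate MAE against a
# zero-order baseline, Frechet distance between deep-feature Gaussians, PSNR,
# and volumetric analysis of segmentations.

# ---- covariate regressor -----------------------------------------------------

#' Train a small residual CNN covariate regressor
#'
#' Predicts the covariate (age by default) from the image. Targets are
#' standardized internally; training minimizes the L1 error with AdamW. The
#' held-out MAE on the `val` split is reported in the returned object.
#'
#' @param cohort cohort table with `train` and `val` splits.
#' @param images optional preloaded `(H, W, N)` array aligned with the cohort.
#' @param covariate column name to regress (default `"age"`).
#' @param widths channel widths of the conv stack.
#' @param epochs,batch_size,learning_rate training controls.
#' @param seed integer seed.
#' @param verbose print per-epoch training loss.
#' @return object of class `covariate_regressor` with the fitted network and
#'   `holdout_mae`.
#' @export
train_covariate_regressor <- function(cohort, images = NULL,
                                      covariate = "age",
                                      widths = c(8, 16, 32), epochs = 12L,
                                      batch_size = 32L, learning_rate = 2e-3,
                                      seed = 1L, verbose = FALSE) {
  y_all <- cohort[[covariate]]
  if (sd(y_all) < 1e-8) stop("degenerate covariate variance in cohort")
  if (is.null(images)) images <- load_cohort_images(cohort)
  tr_idx <- which(cohort$split == "train")
  va_idx <- which(cohort$split == "val")
  if (!length(va_idx)) va_idx <- tr_idx
  mu <- mean(y_all[tr_idx]); s <- sd(y_all[tr_idx])
  net <- convnet_init(widths, out_dim = 1L, seed = seed)
  ps <- params_of(net)
  opt <- adamw_init(ps)
  with_seed(seed, "regressor_training", {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      tot <- 0; nb <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        x <- array(images[, , b, drop = FALSE],
                   c(dim(images)[1], dim(images)[2], 1L, length(b)))
        ad_zero_grads(ps)
        out <- convnet_fwd(net, x)$out
        loss <- op_l1(out, matrix((y_all[b] - mu) / s, 1))
        ad_backward(loss)
        opt <- adamw_step(ps, opt, learning_rate, 1e-5)
        tot <- tot + loss$v; nb <- nb + 1
      }
      if (verbose) message(sprintf("regressor epoch %d: L1 %.4f", ep, tot / nb))
    }
  })
  reg <- structure(list(net = net, covariate = covariate, mu = mu, sd = s),
                   class = "covariate_regressor")
  reg$holdout_mae <- mean(abs(predict(reg, images[, , va_idx, drop = FALSE]) -
                                y_all[va_idx]))
  reg
}

#' Predict the covariate for a stack of images
#'
#' @param object a `covariate_regressor`.
#' @param newdata matrix or `(H, W, N)` array of images in `[0, 1]`.
#' @param ... unused.
#' @return numeric predictions in the covariate's natural units.
#' @export
predict.covariate_regressor <- function(object, newdata, ...) {
  xb <- as_batch(newdata)
  N <- dim(xb)[4]
  preds <- numeric(N)
  for (b in split(seq_len(N), ceiling(seq_len(N) / 64))) {
    out <- convnet_fwd(object$net, xb[, , , b, drop = FALSE])$out
    preds[b] <- drop(out$v)
  }
  preds * object$sd + object$mu
}

#' Predicted-covariate MAE of synthesized images per gap
#'
#' For each requested gap `g` and each evaluation subject, the generator
#' synthesizes the subject at target `a_t = a_s + g` and the regressor's
#' prediction is compared against `a_t` (`MAE = mean |prediction - a_t|`).
#' The zero-order baseline scores the unmodified images against the same
#' shifted targets, so its error grows with `|g|`. Subjects whose target
#' would leave `age_range` are skipped for that gap.
#'
#' @param regressor a [train_covariate_regressor()] fit (or any object with a
#'   `predict` method in covariate units).
#' @param generator a trained [generator_net()].
#' @param images `(H, W, N)` evaluation images.
#' @param covariates their true covariate values.
#' @param gaps numeric vector of gaps (default `c(-20, -15, -10, -5, 5, 10,
#'   15, 20)`).
#' @param age_range admissible covariate range.
#' @return a `data.frame` (class `eval_table`) with one row per gap and
#'   method (`model` / `zero_order`): columns `gap`, `method`, `mae`,
#'   `mae_sd`, `n`.
#' @export
predicted_covariate_mae <- function(regressor, generator, images, covariates,
                                    gaps = c(-20, -15, -10, -5, 5, 10, 15, 20),
                                    age_range = c(45, 82)) {
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  if (dim(images)[3] == 0) stop("empty evaluation set")
  rows <- list()
  pred_orig <- predict(regressor, images)
  for (g in gaps) {
    a_t <- covariates + g
    keep <- which(a_t >= age_range[1] & a_t <= age_range[2])
    if (!length(keep)) next
    syn <- generator_forward(generator, images[, , keep, drop = FALSE],
                             rep(g, length(keep)))
    err_m <- abs(predict(regressor, syn$output) - a_t[keep])
    err_z <- abs(pred_orig[keep] - a_t[keep])
    rows[[length(rows) + 1L]] <- data.frame(
      gap = g, method = c("model", "zero_order"),
      mae = c(mean(err_m), mean(err_z)),
      mae_sd = c(sd(err_m), sd(err_z)), n = length(keep))
  }
  structure(do.call(rbind, rows), class = c("eval_table", "data.frame"))
}

# ---- Frechet distance --------------------------------------------------------

#' Gaussian feature statistics
#'
#' @param mu mean vector; `sigma` covariance matrix (symmetric PSD).
#' @return object of class `feature_stats`.
#' @export
feature_stats <- function(mu, sigma) {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("covariance is not positive semidefinite")
  structure(list(mu = as.numeric(mu), sigma = sigma), class = "feature_stats")
}

# Symmetric PSD matrix square root via eigendecomposition; eigenvalues in
# [-1e-8, 0) are clamped to 0, anything lower is an error.
sqrtm_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("matrix has negative eigenvalues")
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two feature Gaussians
#'
#' `||mu_a - mu_b||^2 + tr(Sigma_a + Sigma_b - 2 (Sigma_a Sigma_b)^(1/2))`,
#' with the matrix square root computed through the symmetrized product
#' `Sigma_a^(1/2) Sigma_b Sigma_a^(1/2)` for numerical stability.
#'
#' @param stats_a,stats_b [feature_stats()] objects of equal dimension.
#' @return non-negative scalar distance.
#' @export
fid <- function(stats_a, stats_b) {
  stopifnot(inherits(stats_a, "feature_stats"),
            inherits(stats_b, "feature_stats"))
  if (length(stats_a$mu) != length(stats_b$mu))
    stop("feature dimension mismatch")
  a2 <- sqrtm_psd(stats_a$sigma)
  cross <- sqrtm_psd(a2 %*% stats_b$sigma %*% a2)
  v <- sum((stats_a$mu - stats_b$mu)^2) + sum(diag(stats_a$sigma)) +
    sum(diag(stats_b$sigma)) - 2 * sum(diag(cross))
  max(v, 0)
}

#' Train a small CNN feature extractor for the Frechet distance
#'
#' A compact convolutional classifier trained to separate covariate quantile
#' bins of the cohort; its penultimate (pooled) layer provides the features
#' whose Gaussian statistics enter [fid()].
#'
#' @inheritParams train_covariate_regressor
#' @param n_bins number of covariate quantile bins (default 4).
#' @return object of class `feature_extractor`.
#' @export
train_feature_extractor <- function(cohort, images = NULL, covariate = "age",
                                    n_bins = 4L, widths = c(8, 16, 32),
                                    epochs = 8L, batch_size = 32L,
                                    learning_rate = 2e-3, seed = 1L) {
  if (is.null(images)) images <- load_cohort_images(cohort)
  y <- cohort[[covariate]]
  qs <- quantile(y, probs = seq(0, 1, length.out = n_bins + 1))
  labels <- findInterval(y, qs[-c(1, n_bins + 1)]) + 1L
  net <- convnet_init(widths, out_dim = n_bins, seed = seed)
  ps <- params_of(net)
  opt <- adamw_init(ps)
  tr_idx <- which(cohort$split == "train")
  if (!length(tr_idx)) tr_idx <- seq_len(nrow(cohort))
  with_seed(seed, "extractor_training", {
    for (ep in seq_len(epochs)) {
      for (b in split(sample(tr_idx), ceiling(seq_along(tr_idx) / batch_size))) {
        x <- array(images[, , b, drop = FALSE],
                   c(dim(images)[1], dim(images)[2], 1L, length(b)))
        ad_zero_grads(ps)
        loss <- op_softmax_ce(convnet_fwd(net, x)$out, labels[b])
        ad_backward(loss)
        opt <- adamw_step(ps, opt, learning_rate, 1e-5)
      }
    }
  })
  structure(list(net = net, dim = tail(widths, 1), n_bins = n_bins),
            class = "feature_extractor")
}

#' Extract Gaussian feature statistics from an image set
#'
#' Penultimate-layer features of the extractor; when the set is not larger
#' than the feature dimension, the covariance is shrunk toward a scaled
#' identity so it stays positive semidefinite.
#'
#' @param images matrix or `(H, W, N)` array.
#' @param extractor a [train_feature_extractor()] fit.
#' @return a [feature_stats()] object.
#' @export
extract_features <- function(images, extractor) {
  xb <- as_batch(images)
  N <- dim(xb)[4]
  if (N < 2) stop("need at least 2 images for feature statistics")
  feats <- matrix(0, N, extractor$dim)
  for (b in split(seq_len(N), ceiling(seq_len(N) / 64)))
    feats[b, ] <- t(convnet_fwd(extractor$net,
                                xb[, , , b, drop = FALSE])$features$v)
  mu <- colMeans(feats)
  sig <- cov(feats)
  p <- ncol(feats)
  if (N <= p) {
    lam <- min(1, p / N)
    sig <- (1 - lam) * sig + lam * (sum(diag(sig)) / p) * diag(p)
  }
  feature_stats(mu, sig)
}

# ---- PSNR --------------------------------------------------------------------

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels; identical images return `Inf`.
#'
#' @param a,b images of identical shape.
#' @param peak peak intensity (1.0 for images in `[0, 1]`).
#' @return scalar in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, peak = 1.0) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# ---- volumetric analysis -----------------------------------------------------

#' Volumetric metrics from a label mask
#'
#' LV cavity area (pixel count), mean interventricular septum width (width of
#' the myocardium band between the LV and RV cavities along horizontal
#' scanlines crossing both, averaged over the central half of qualifying
#' scanlines), and — when an ES mask is supplied — the ejection fraction
#' `(area_ED - area_ES) / area_ED`.
#'
#' @param mask integer label mask (phantom coding: 1 LV, 2 myocardium, 3 RV).
#' @param es_mask optional end-systolic mask paired with the (ED) `mask`.
#' @return list with `lv_area`, `septum_width` and optionally
#'   `ejection_fraction`.
#' @export
volumetric_metrics <- function(mask, es_mask = NULL) {
  for (lab in c(lv = 1L, myo = 2L, rv = 3L)) {
    if (!any(mask == lab))
      stop(sprintf("mask is missing label %d (%s)", lab,
                   names(phantom_labels)[phantom_labels == lab]))
  }
  lv_area <- sum(mask == 1L)
  rows <- which(apply(mask == 1L, 1, any) & apply(mask == 3L, 1, any))
  widths <- vapply(rows, function(r) {
    lv_max <- max(which(mask[r, ] == 1L))
    rv_cols <- which(mask[r, ] == 3L)
    rv_cols <- rv_cols[rv_cols > lv_max]
    if (!length(rv_cols)) return(NA_real_)
    rv_min <- min(rv_cols)
    if (rv_min - lv_max < 2) return(0)
    sum(mask[r, (lv_max + 1):(rv_min - 1)] == 2L)
  }, numeric(1))
  ok <- rows[!is.na(widths) & widths > 0]
  widths <- widths[!is.na(widths) & widths > 0]
  if (!length(widths)) stop("no scanline crosses both LV and RV cavities")
  # central half of qualifying scanlines: oblique crossings near the cavity
  # poles overestimate the radial septum width
  qs <- quantile(seq_along(widths), c(0.25, 0.75))
  central <- widths[seq_along(widths) >= qs[1] & seq_along(widths) <= qs[2]]
  out <- list(lv_area = lv_area, septum_width = mean(central))
  if (!is.null(es_mask)) {
    es_area <- sum(es_mask == 1L)
    out$ejection_fraction <- (lv_area - es_area) / lv_area
  }
  out
}

#' Normalized variation of a metric relative to an original population
#'
#' `(m_i - mean(original)) / mean(original)` per subject, the normalization
#' used for the volumetric box plots.
#'
#' @param metric_values metric values of the (possibly synthesized) subjects.
#' @param original_values metric values of the original population.
#' @return numeric vector of normalized differences.
#' @export
normalized_variation <- function(metric_values, original_values) {
  if (!length(original_values)) stop("original_values is empty")
  m0 <- mean(original_values)
  if (abs(m0) < .Machine$double.eps) stop("original mean is zero")
  (metric_values - m0) / m0
}

# ---- rule-based phantom segmentation ------------------------------------------

#' Segment a phantom-domain image into the label coding
#'
#' Rule-based segmentation exploiting the phantom's per-region intensity
#' bands: each pixel is assigned to the nearest band, then each region is
#' cleaned to its largest connected component with holes filled, painted
#' back-to-front. Deterministic.
#'
#' @param image matrix in `[0, 1]` from the phantom domain.
#' @param min_area smallest accepted region area in pixels.
#' @return integer label mask.
#' @export
segment_generated <- function(image, min_area = 4L) {
  ti <- phantom_intensities()
  bands <- c(bg = ti[["bg"]], myo = ti[["myo"]], ra = ti[["ra"]],
             la = ti[["la"]], rv = ti[["rv"]], lv = ti[["lv"]],
             aorta = ti[["aorta"]], fat = ti[["fat"]])
  dd <- abs(outer(as.vector(image), bands, "-"))
  raw_lab <- names(bands)[max.col(-dd)]
  raw <- matrix(raw_lab, nrow(image), ncol(image))
  out <- matrix(0L, nrow(image), ncol(image))
  found <- FALSE
  for (lab in c("myo", "lv", "rv", "la", "ra", "aorta")) {
    m <- raw == lab
    if (!any(m)) next
    cc <- EBImage::bwlabel(m)
    sizes <- tabulate(cc[cc > 0])
    if (!length(sizes) || max(sizes) < min_area) next
    keep <- cc == which.max(sizes)
    keep <- EBImage::fillHull(keep)
    out[keep > 0] <- phantom_labels[[lab]]
    found <- TRUE
  }
  if (!found) stop("no region found above the minimum area")
  out
}

# ---- assembled evaluation table ----------------------------------------------

#' Full per-gap evaluation table (MAE, FID, PSNR)
#'
#' @param model a `cardiosynth_model` (or a generator).
#' @param images,covariates evaluation images and covariates.
#' @param gaps covariate gaps to evaluate.
#' @param regressor a covariate regressor; `extractor` a feature extractor
#'   (optional: FID columns are omitted when absent).
#' @param age_range admissible covariate range.
#' @return `eval_table` data.frame with one row per gap: model and zero-order
#'   MAE, FID between synthesized and original feature statistics, mean PSNR.
#' @export
evaluate_model <- function(model, images, covariates, gaps, regressor,
                           extractor = NULL, age_range = c(45, 82)) {
  gen <- if (inherits(model, "cardiosynth_model")) model$generator else model
  mae_tab <- predicted_covariate_mae(regressor, gen, images, covariates,
                                     gaps, age_range)
  rows <- list()
  stats_orig <- if (!is.null(extractor)) extract_features(images, extractor)
  for (g in gaps) {
    a_t <- covariates + g
    keep <- which(a_t >= age_range[1] & a_t <= age_range[2])
    if (!length(keep)) next
    syn <- generator_forward(gen, images[, , keep, drop = FALSE],
                             rep(g, length(keep)))
    ps <- vapply(seq_along(keep), function(i)
      psnr(images[, , keep[i]], syn$output[, , i]), numeric(1))
    mm <- mae_tab[mae_tab$gap == g & mae_tab$method == "model", ]
    mz <- mae_tab[mae_tab$gap == g & mae_tab$method == "zero_order", ]
    rows[[length(rows) + 1L]] <- data.frame(
      gap = g, n = mm$n, mae_model = mm$mae, mae_model_sd = mm$mae_sd,
      mae_zero_order = mz$mae, mae_zero_order_sd = mz$mae_sd,
      fid = if (!is.null(extractor))
        fid(extract_features(syn$output, extractor), stats_orig) else NA_real_,
      psnr_mean = mean(ps[is.finite(ps)]))
  }
  structure(do.call(rbind, rows), class = c("eval_table", "data.frame"))
}

#' Monotonicity of measured morphology in the requested covariate gap
#'
#' Synthesizes every evaluation subject at each requested gap, segments the
#' outputs with [segment_generated()], measures LV area and septum width with
#' [volumetric_metrics()], and computes pooled Spearman correlations between
#' the gap and the per-subject-centered measurements (each subject's
#' available measurements are centered on their own mean, so subjects with
#' unsegmentable outputs at some gaps still contribute their remaining
#' cells). The phantom analogue of a volumetric aging analysis: septum width
#' should rise and LV area fall with the gap.
#'
#' @param generator a trained generator.
#' @param images `(H, W, N)` evaluation images.
#' @param gaps numeric vector of requested gaps (default
#'   `c(-20, -10, 0, 10, 20)`).
#' @return list with `septum_rho`, `lv_area_rho`, `n_pairs` (usable
#'   subject-gap cells), `n_subjects`, and the raw measurement matrices
#'   `septum` and `lv_area` (subjects x gaps).
#' @export
gap_monotonicity <- function(generator, images, gaps = c(-20, -10, 0, 10, 20)) {
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[3]
  sw <- la <- matrix(NA_real_, n, length(gaps))
  for (j in seq_along(gaps)) {
    syn <- generator_forward(generator, images, rep(gaps[j], n))
    out <- if (n == 1L) array(syn$output, c(dim(images)[1:2], 1L)) else syn$output
    for (i in seq_len(n)) {
      m <- tryCatch(volumetric_metrics(segment_generated(out[, , i])),
                    error = function(e) list(septum_width = NA_real_,
                                             lv_area = NA_real_))
      sw[i, j] <- m$septum_width
      la[i, j] <- m$lv_area
    }
  }
  pooled_rho <- function(x) {
    ctr <- x - rowMeans(x, na.rm = TRUE)
    keep <- !is.na(ctr) & rowSums(!is.na(x)) >= 2
    if (sum(keep) < 10) return(NA_real_)
    cor(matrix(gaps, n, length(gaps), byrow = TRUE)[keep], ctr[keep],
        method = "spearman")
  }
  list(septum_rho = pooled_rho(sw), lv_area_rho = pooled_rho(la),
       n_pairs = sum(!is.na(sw)), n_subjects = n, septum = sw, lv_area = la)
}
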