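# Dataset-debiasing experiment and alternative covariate tasks.
#
# An age-imbalanced dataset (e.g. 90% of subjects younger than 70) is
# gradually augmented with synthetically age-shifted images of majority-side
# subjects moved into the minority age region; a fresh covariate regressor is
# trained per configuration and evaluated on a fixed balanced held-out set.

#' Specification of an imbalanced dataset
#'
#' @param n_total dataset size (default 1000).
#' @param threshold age threshold separating the two sides (years).
#' @param minority_side `"older"` or `"younger"`: which side is the 10% side.
#' @param minority_fraction fraction of subjects on the minority side.
#' @param synth_fractions synthetic-augmentation fractions of `n_total`.
#' @return list of class `imbalance_spec`.
#' @export
imbalance_spec <- function(n_total = 1000L, threshold = 70,
                           minority_side = c("older", "younger"),
                           minority_fraction = 0.10,
                           synth_fractions = c(0.01, 0.05, 0.10, 0.25)) {
  minority_side <- match.arg(minority_side)
  stopifnot(minority_fraction > 0, minority_fraction < 0.5,
            all(synth_fractions > 0), all(synth_fractions < 1))
  structure(list(n_total = as.integer(n_total), threshold = threshold,
                 minority_side = minority_side,
                 minority_fraction = minority_fraction,
                 synth_fractions = synth_fractions),
            class = "imbalance_spec")
}

side_of <- function(ages, threshold) ifelse(ages >= threshold, "older",
                                            "younger")

#' Subsample a cohort into an imbalanced dataset
#'
#' Draws exactly `round(n_total * (1 - minority_fraction))` majority-side and
#' the remaining minority-side subjects, without replacement.
#'
#' @param cohort cohort table.
#' @param spec an [imbalance_spec()].
#' @param seed integer seed.
#' @return cohort table of `n_total` rows (attribute `base_dir` preserved).
#' @export
build_imbalanced_dataset <- function(cohort, spec, seed = 1L) {
  sides <- side_of(cohort$age, spec$threshold)
  n_min <- round(spec$n_total * spec$minority_fraction)
  n_maj <- spec$n_total - n_min
  min_idx <- which(sides == spec$minority_side)
  maj_idx <- which(sides != spec$minority_side)
  if (length(min_idx) < n_min || length(maj_idx) < n_maj)
    stop(sprintf(paste0("cohort cannot satisfy the spec: need %d minority ",
                        "(have %d) and %d majority (have %d) subjects"),
                 n_min, length(min_idx), n_maj, length(maj_idx)))
  sel <- with_seed(seed, "imbalanced_selection",
                   c(sample(min_idx, n_min), sample(maj_idx, n_maj)))
  out <- cohort[sort(sel), ]
  out$synthetic <- 0L
  attr(out, "base_dir") <- attr(cohort, "base_dir")
  class(out) <- class(cohort)
  out
}

#' Augment a dataset with synthetically covariate-shifted subjects
#'
#' Adds `round(fraction * n)` synthetic images created by shifting randomly
#' chosen majority-side subjects into the minority age region; the synthetic
#' rows carry the target age as their label and are flagged `synthetic = 1`.
#'
#' @param dataset an (imbalanced) cohort table.
#' @param generator a trained generator.
#' @param fraction fraction of `nrow(dataset)` to add (0 returns the dataset
#'   unchanged, with a warning if a nonzero count was implied).
#' @param spec the [imbalance_spec()] that produced the dataset (defines the
#'   minority region).
#' @param seed integer seed.
#' @param out_dir directory for the synthetic images (default: subdirectory
#'   `synthetic` of the dataset's base directory).
#' @param age_range covariate range of the cohort.
#' @return the augmented cohort table.
#' @export
augment_with_synthetic <- function(dataset, generator, fraction, spec,
                                   seed = 1L, out_dir = NULL,
                                   age_range = c(45, 82)) {
  if (fraction == 0) {
    warning("fraction 0: returning the dataset unchanged")
    return(dataset)
  }
  base <- attr(dataset, "base_dir")
  if (is.null(out_dir)) out_dir <- file.path(base, "synthetic")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_add <- round(fraction * nrow(dataset))
  minority_iv <- if (spec$minority_side == "older")
    c(spec$threshold, age_range[2]) else c(age_range[1], spec$threshold)
  maj_rows <- which(side_of(dataset$age, spec$threshold) != spec$minority_side &
                      dataset$synthetic == 0L)
  pick <- with_seed(seed, "synthetic_augmentation", {
    src <- sample(maj_rows, n_add, replace = TRUE)
    a_t <- runif(n_add, minority_iv[1], minority_iv[2])
    list(src = src, a_t = a_t)
  })
  new_rows <- dataset[pick$src, ]
  for (i in seq_len(n_add)) {
    r <- pick$src[i]
    img <- read_image(file.path(base, dataset$image_path[r]))
    syn <- generator_forward(generator, img, pick$a_t[i] - dataset$age[r])
    rel <- sprintf("synthetic/%s_to_%05.1f_%03d.png", dataset$subject_id[r],
                   pick$a_t[i], i)
    write_image(syn$output, file.path(base, rel))
    new_rows$image_path[i] <- rel
    new_rows$mask_path[i] <- NA_character_
    new_rows$age[i] <- pick$a_t[i]
    new_rows$subject_id[i] <- sprintf("%s_syn%03d", dataset$subject_id[r], i)
    new_rows$synthetic[i] <- 1L
  }
  out <- rbind(dataset, new_rows)
  attr(out, "base_dir") <- base
  class(out) <- class(dataset)
  out
}

#' Run the debiasing data-augmentation experiment
#'
#' For each seed, constructs the imbalanced dataset, augments it with each
#' synthetic fraction, trains a fresh covariate regressor per configuration
#' and evaluates its MAE on a fixed balanced held-out set (disjoint subjects).
#' A balanced dataset of the same size is trained per seed as reference.
#'
#' @param cohort full cohort table.
#' @param spec an [imbalance_spec()].
#' @param generator trained generator used for the synthetic samples.
#' @param seeds integer vector of repetition seeds.
#' @param fractions synthetic fractions to evaluate (0 is always included).
#' @param heldout_n size of the balanced held-out evaluation set.
#' @param regressor_args list of arguments passed to
#'   [train_covariate_regressor()] (e.g. `epochs`, `widths`).
#' @param include_balanced train the balanced reference dataset as well.
#' @return list with `raw` (per-seed MAEs) and `summary` (mean and sd per
#'   dataset/fraction), both data.frames.
#' @export
run_debias_experiment <- function(cohort, spec, generator, seeds = 1:5,
                                  fractions = spec$synth_fractions,
                                  heldout_n = 200L,
                                  regressor_args = list(),
                                  include_balanced = TRUE) {
  base <- attr(cohort, "base_dir")
  sides <- side_of(cohort$age, spec$threshold)
  held <- with_seed(seeds[1], "heldout_selection", {
    per <- heldout_n %/% 2
    c(sample(which(sides == "older"), per),
      sample(which(sides == "younger"), heldout_n - per))
  })
  heldout <- cohort[held, ]
  attr(heldout, "base_dir") <- base
  pool <- cohort[-held, ]
  attr(pool, "base_dir") <- base
  class(pool) <- class(heldout) <- class(cohort)
  held_imgs <- load_cohort_images(heldout)
  rows <- list()
  fit_mae <- function(ds, seed) {
    if (length(intersect(ds$subject_id, heldout$subject_id)))
      stop("train/test subject overlap in the debias experiment")
    ds$split <- "train"
    args <- c(list(cohort = ds, seed = seed), regressor_args)
    reg <- do.call(train_covariate_regressor, args)
    mean(abs(predict(reg, held_imgs) - heldout$age))
  }
  for (seed in seeds) {
    ds0 <- build_imbalanced_dataset(pool, spec, seed)
    for (f in sort(unique(c(0, fractions)))) {
      ds <- if (f == 0) ds0
            else augment_with_synthetic(ds0, generator, f, spec, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = "imbalanced", fraction = f, seed = seed,
        mae = fit_mae(ds, seed))
    }
    if (include_balanced) {
      bal <- with_seed(seed, "balanced_selection", {
        per <- spec$n_total %/% 2
        c(sample(which(side_of(pool$age, spec$threshold) == "older"), per),
          sample(which(side_of(pool$age, spec$threshold) == "younger"),
                 spec$n_total - per))
      })
      dsb <- pool[bal, ]
      attr(dsb, "base_dir") <- base
      class(dsb) <- class(pool)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = "balanced", fraction = NA_real_, seed = seed,
        mae = fit_mae(dsb, seed))
    }
  }
  raw <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(raw, paste(raw$dataset, raw$fraction)),
                                   function(d) data.frame(
                                     dataset = d$dataset[1],
                                     fraction = d$fraction[1],
                                     mae_mean = mean(d$mae),
                                     mae_sd = sd(d$mae), n_seeds = nrow(d))))
  rownames(summary) <- NULL
  list(raw = raw, summary = summary[order(summary$dataset, summary$fraction), ])
}

#' Configuration for the alternative covariate tasks
#'
#' `"bmi"` conditions the model on the body-mass-index gap (range +-8,
#' evaluation bins as in the BMI protocol); `"phase"` uses a binary phase
#' indicator (ED = 0, ES = 1) with gaps in `{-1, 0, +1}`, evaluated by the
#' root mean square error between generated images and the paired real ES
#' frames; `"age"` is the default main task.
#'
#' @param task `"age"`, `"bmi"` or `"phase"`.
#' @return list with `covariate`, `covariate_mode`, `gap_min`, `gap_max`,
#'   `eval_gaps`, `covariate_range` and the paired-comparison flag.
#' @export
configure_alternative_task <- function(task = c("age", "bmi", "phase")) {
  task <- match.arg(task)
  switch(task,
    age = list(task = "age", covariate = "age", covariate_mode = "age",
               gap_min = -25, gap_max = 25,
               eval_gaps = c(-20, -15, -10, -5, 5, 10, 15, 20),
               covariate_range = c(45, 82), paired_rmse = FALSE),
    bmi = list(task = "bmi", covariate = "bmi", covariate_mode = "bmi",
               gap_min = -8, gap_max = 8,
               eval_gaps = c(-8, -6, -4, -2, -1, 0, 1, 2, 4, 6, 8),
               covariate_range = c(18, 38), paired_rmse = FALSE),
    phase = list(task = "phase", covariate = "phase_index",
                 covariate_mode = "phase", gap_min = -1, gap_max = 1,
                 eval_gaps = c(-1, 0, 1), covariate_range = c(0, 1),
                 paired_rmse = TRUE))
}
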