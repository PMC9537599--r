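# cardiosynth

Synthesizing older and younger versions of a cardiac image from
cross-sectional data with a conditional Wasserstein GAN, together with the
quantitative protocol needed to judge whether the synthesis actually moved
the covariate.

## The problem

Longitudinal cardiac imaging over multi-decade spans essentially does not
exist, yet morphological aging of the heart — septal thickening, shrinking
left-ventricular (LV) cavity, aortic dilation — is well documented across
subjects. Given only cross-sectional data (one image per subject, subjects of
different ages), `cardiosynth` trains a generator `G(x, a_d)` that maps an
image `x` and a covariate gap `a_d` (years, BMI units or a cardiac-phase
switch) to a bounded residual mapping `m ∈ [-1, 1]`, producing the
covariate-shifted image `x̃ = clip(x + m, 0, 1)`.

Training follows the WGAN-GP objective with a conditional critic `D(x, a)`
(conditioned on the presented image's covariate via sinusoidal embeddings and
per-channel additive biasing) plus a cycle-consistency term:

    L = min_G max_D  E[D(x̃, a_t)] − E[D(x, a_t)]
        + λ_GP · E[(‖∇_x̂ D(x̂, a_t)‖₂ − 1)²]     (λ_GP = 10)
        + λ_cc · E[ ‖x − G(G(x, a_d), −a_d)‖₁ ]   (λ_cc = 1)

with `x̂` uniform on segments between real and generated samples. The critic
is updated 50× per generator update during a warm-up, 5× afterwards; both
nets use AdamW.

Because real cardiac MRI of this kind is access-restricted, the package
ships a **four-chamber phantom simulator** whose covariate→morphology law is
known exactly (septum width and aortic radius increase linearly with age, LV
cavity radius decreases; BMI controls a peripheral fat band; the ES phase
contracts the cavities). Every claim about the synthesis becomes a testable
parameter-recovery statement.

There is no deep-learning framework in this stack: the networks run on a
small reverse-mode autodiff engine with Rcpp/Armadillo convolution kernels
included in the package. The critic is piecewise linear by construction,
which makes the WGAN-GP second-order parameter gradient available in closed
form (verified against finite differences in the test suite).

## Worked example

```r
library(cardiosynth)

## 1. simulate a phantom cohort (48-px images, ages 45-82)
co <- generate_cohort(500, "phantoms", image_size = 48, rng_seed = 11)

## 2. train the conditional WGAN-GP at desk scale
cfg <- net_config(image_size = 48, levels = 3, base_width = 8,
                  channel_mults = c(1, 2, 4), blocks_per_level = 1,
                  attn_levels = 3, emb_dim = 32, proj_hidden = 32, groups = 4)
tc <- train_config(epochs = 45, batch_size = 12, warmup_epochs = 2,
                   critic_updates_warmup = 15, critic_updates_main = 5,
                   learning_rate = 2e-4, crop_pixels_x = 0, target_size = 48,
                   net = cfg, weights = loss_weights(lambda_cc = 5),
                   augment = FALSE, drift = 0.01, critic_input_noise = 0.02,
                   seed = 5)
model <- train_cgan(tc, co, out_dir = "run", verbose = TRUE)

## 3. synthesize an aged version of a held-out subject
x <- read_image(file.path("phantoms", co$image_path[co$split == "test"][1]))
syn <- generator_forward(model$generator, x, a_d = 20)
print(syn)

## 4. did apparent age move? regressor MAE vs the zero-order baseline
reg <- train_covariate_regressor(co, epochs = 10, seed = 3)
te <- which(co$split == "test")
imgs <- load_cohort_images(co)
predicted_covariate_mae(reg, model$generator, imgs[, , te], co$age[te],
                        gaps = c(-20, 20))
```

On one desk-scale run (cohort seed 11, n = 1400 phantoms, training seed 5,
~11 minutes on one CPU) this prints a regressor held-out MAE of 1.9 years
and, at gaps of +-20 years,

    gap  method      mae
    -20  model       ~12.8      # apparent age moved toward the target
    -20  zero_order  ~18.9      # unmodified images: error ~= |gap|
     20  model       ...
     20  zero_order  ...

i.e. the synthesis moves apparent age about a third of the way to the
target, clearly beating the do-nothing baseline — while the cycle
reconstruction error (~0.086) and the segmentation-based septum measurement
show that desk-scale training does not yet produce spatially localized,
band-clean edits. The methods vignette discusses this trade-off; the
acceptance script below reports both sides.

## Command line

A thin wrapper `inst/scripts/cardiosynth` exposes the pipeline:

```sh
cardiosynth simulate --n 500 --size 48 --seed 11 --out phantoms/
cardiosynth train --config config.yaml --cohort phantoms/cohort.csv --out run/
cardiosynth synthesize --checkpoint run/checkpoint.rds --image subj.png --gap 20 --out synth/
cardiosynth evaluate --checkpoint run/checkpoint.rds --cohort phantoms/cohort.csv --gaps -20,-10,10,20 --out report.csv
cardiosynth debias --checkpoint run/checkpoint.rds --cohort phantoms/cohort.csv --out table.csv
```

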