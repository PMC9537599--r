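---
title: "Modeling cardiac aging with a conditional WGAN-GP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cardiac aging with a conditional WGAN-GP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiosynth)
```

## The problem

Morphological cardiac aging — septal thickening, reduced left-ventricular
(LV) cavity size, aortic dilation — is documented across subjects, but
longitudinal image series spanning more than about a decade do not exist.
`cardiosynth` learns a covariate-conditioned image-to-image mapping from
*cross-sectional* data: given one 2-D grayscale cardiac image and a covariate
gap `a_d` (years of age, BMI units, or a cardiac-phase switch), the generator
produces a bounded residual mapping `m` in `[-1, 1]` and the covariate-shifted
image `clip(x + m, 0, 1)`. Training needs only (image, covariate) pairs from
different subjects.

## Model

**Generator.** A U-Net of residual blocks with single-head spatial
self-attention at the coarsest resolutions, the backbone family popularized
by diffusion models. The covariate gap enters through a Transformer-style
sinusoidal embedding,

    e[2i]   = sin(a / C^(2i/d)),
    e[2i+1] = cos(a / C^(2i/d)),    i = 0 .. d/2 - 1,  C = 10000,

projected per residual block to one scalar per feature channel and *added*
channel-wise before the block's first group normalization ("conditional
biasing"). Each block owns its projection, so conditioning can be fitted per
resolution. The output head is a `tanh`: a smooth saturating bound on the
mapping rather than a hard clip, so gradients keep flowing near the bounds.

**Critic.** A strided convolutional encoder with leaky-ReLU activations,
additive conditional biasing of every layer (embedding of the *presented*
covariate: the true covariate for real images, the target for synthesized
ones), adaptive mean pooling and a dense head giving one scalar score. Two
deliberate differences from the generator's residual blocks:

* *No normalization layers.* The gradient penalty below is defined per
  sample; batch- or group-coupled statistics change the input-gradient and
  are avoided in WGAN-GP critics.
* *No attention, piecewise-linear activations only.* With leaky-ReLU
  activation patterns fixed, the critic is locally linear in its input. Its
  input gradient is then a composition of linear maps, and the parameter
  gradient of the gradient penalty has a closed form obtained by
  backpropagating through that composition — the package computes the WGAN-GP
  second-order term exactly (almost everywhere) without generic
  double-backprop machinery. The test suite checks this against central
  finite differences of the composed critic loss.

**Objective.** The critic minimizes

    E[D(x_gen, a_t)] - E[D(x_real, a_real)]
      + lambda_GP * E[(||grad_xhat D(xhat, a_t)||_2 - 1)^2]

with `xhat = eps * x_real + (1 - eps) * x_gen`, `eps ~ U(0, 1)` drawn
independently per batch element, and `lambda_GP = 10`. The generator
minimizes

    -E[D(x_gen, a_t)] + lambda_cc * E[ |x - G(G(x, a_d), -a_d)|_1 ]

with `lambda_cc = 1` at full scale: the cycle term demands that aging by
`a_d` and rejuvenating by `-a_d` reconstructs the input. Alternating
optimization realizes the min-max; the critic is updated 50 times per
generator update during a 20-epoch warm-up, 5 times afterwards. Both networks
use decoupled-weight-decay Adam (learning rate and weight decay `1e-4`,
betas 0.9/0.999, batch 12).

A few implementation choices stabilize the estimate and are worth stating.
First, the critic's real batch is *age-matched* to the sampled target
covariates (drawn among the nearest-age subjects, presented with their own
true age). If the real and generated terms presented systematically
different covariate distributions, any pure function of the covariate inside
the critic would grow the Wasserstein core without bound — a direction the
gradient penalty, which only constrains image gradients, cannot touch; age
matching removes that degenerate direction while keeping every real image
paired with its true covariate. Second, a small score-drift term
(`drift * mean(D^2)`, default `1e-3`, both branches) pins the score scale,
which the Wasserstein objective leaves unidentified. Third, Gaussian
*instance noise* (`critic_input_noise`, default sd 0.02) is added to both
real and generated images before they reach the critic during training:
without it the critic wins by detecting low-amplitude synthesis texture
("fingerprints") instead of structure, and the generator receives no useful
gradient. Finally, an exponential moving average of the generator weights
can be kept for evaluation (`ema_decay`; off by default — averaging
suppresses update noise but also dampens a covariate response that is still
being learned).

## Preprocessing, augmentation, gap sampling

Raw images are center-cropped by 90 columns (odd splits remove the extra
column on the left), resized bilinearly to 128^2 and min-max rescaled to
`[0, 1]`; constant images map to zeros. Training-time augmentation applies,
each with probability 1/2: a low-order polynomial multiplicative bias field
(coefficients within ±5%), a monotone piecewise-linear histogram remap
(control-point jitter ±0.04), and a gamma contrast adjustment
(`gamma` in `[0.9, 1.12]`), re-clipping afterwards. The magnitudes are mild by
design: they cover scanner-like intensity variation without erasing the
intensity structure the evaluation reads out. Both the generator inputs and
the critic's real batch are augmented. Covariate gaps are drawn uniformly on
`[-25, +25]` years, truncated so the target stays inside the cohort's age
range (the training-time gap law is otherwise a free design choice).

## The phantom cohort

Real cardiac MRI of this kind is access-restricted, so the package ships a
four-chamber phantom whose covariate-to-morphology law is known exactly —
the point is not realism but *testability*: every downstream claim
("synthesized images look older") becomes a parameter-recovery statement.
At a reference side length of 128 px, with age `t = age - 45`:

* interventricular septum width `5 + 0.15 t` px (thickens with age),
* LV cavity radius `24 - 0.15 t` px (shrinks),
* aortic radius `6 + 0.1 t` px (dilates),

so a 20-year gap moves each structure by 2-4 px (per-decade effect sizes are
not quantified in the cardiac-aging literature at this granularity; these
slopes are free parameters chosen for measurability). The RV cavity is an
annular crescent concentric with the LV, which keeps the myocardium band
between the cavities at constant radial width — the rendered septum is
measurable to within 1 px by scanline counting. BMI controls a peripheral
fat-band width; the ES phase contracts the cavities (LV radius × 0.70, an
ejection fraction near 0.5) and thickens the myocardium. Per-subject Gaussian
jitter (for example 0.5 px on the LV radius, 3 degrees rotation) and additive
pixel noise (sd 0.02) make cohorts non-degenerate; ages follow the cohort
distribution `truncnorm(64.1, 7.7)` on `[45, 82]`. Tissue intensity bands
(background 0.05, myocardium 0.40, RA 0.55, LA 0.66, RV 0.78, LV 0.90, aorta
0.98) are separated by at least 4 noise standard deviations, which is what
makes the rule-based segmentation (nearest band, largest connected component,
hole filling) reliable.

What the phantom does **not** emulate: anatomical shape variability beyond
ellipse parameters, MR physics (coil bias beyond the augmentation model,
k-space artifacts), pathology, 3-D structure, and sex-specific morphology
(sex is carried as metadata only — the model is deliberately not
sex-conditioned). Passing the phantom battery therefore demonstrates that
the *machinery* recovers a known covariate-morphology law end to end; it
does not certify performance on clinical images.

## Evaluation protocol

* **Predicted-covariate MAE** (per gap bin): a small residual CNN regressor
  is trained on the cohort; for each gap `g`, the generator synthesizes each
  evaluation subject at `a_t = a_s + g` and `MAE = mean |reg(x~) - a_t|`.
  The *zero-order* baseline scores the unmodified image against the shifted
  target, so its error grows as `|g|`; any model that beats it has moved
  apparent age in the right direction.
* **Frechet distance** between Gaussian fits of deep features of synthesized
  vs original sets. The extractor is a small CNN classifier over cohort age
  quartiles (a scale-appropriate stand-in for a large pretrained classifier;
  the interface is identical). The matrix square root is computed through the
  symmetrized product `S_a^(1/2) S_b S_a^(1/2)` by eigendecomposition;
  eigenvalues in `[-1e-8, 0)` are clamped, lower ones raise an error. When a
  feature set is not larger than the feature dimension, the covariance is
  shrunk toward a scaled identity.
* **PSNR** (`10 log10(peak^2 / MSE)`, peak 1.0, `Inf` for identical images).
* **Volumetric analysis**: LV area, scanline septum width and (for ED/ES
  pairs) ejection fraction from segmentations of original and synthesized
  images, reported as normalized variation against the mean of the original
  population (population-mean reference; the per-subject difference is
  available as an option).
* **Debiasing experiment**: an imbalanced dataset (e.g. 90% of subjects
  younger than 70) is augmented with 1-25% synthetically age-shifted
  majority-side subjects moved into the minority region (source subjects
  drawn uniformly from the majority side, targets uniform over the minority
  interval — the construction is otherwise a free choice); a fresh regressor
  per configuration is evaluated on a fixed balanced held-out set of 200
  subjects (always disjoint by subject id), over 5 seeds.

## Scaled-down study sizes

All stochastic end-to-end checks run at desk scale, chosen as the package's
own study design: training at 48^2 with base width 8, one residual block per
level, attention at the coarsest level, ~340 training phantoms, 45 epochs
(2 warm-up epochs at 15 critic updates per generator update, then 5:1),
learning rate 2e-4 and `lambda_cc = 5`, augmentation off (the phantom domain
has no scanner variation to emulate and the intensity bands carry the
evaluation signal). The larger cycle weight at this scale compensates for a
critic that sees orders of magnitude fewer images than a fully trained one:
with a weak critic the adversarial gradient field is noisy off the data
manifold, and the cycle anchor keeps the generator near the manifold where
the critic is informative. At full scale (128^2, hundreds of epochs) the
defaults revert to the protocol values (`lambda_cc = 1`, learning rate 1e-4,
20 warm-up epochs at 50:1, augmentation on).

The desk-scale runs expose a genuine trade-off that the full-scale protocol
does not face. The covariate response the generator first learns is a
*global intensity* proxy for age (the phantom's mean intensity falls as the
bright LV pool shrinks and the dark myocardium grows), not a spatially
localized boundary edit; spatial specificity requires far more critic and
generator updates than a single-CPU budget provides. A small cycle weight
admits the (crude, image-degrading) global response; a large one collapses
the generator to the identity mapping before any response forms. The
configuration above sits at the measured optimum of that trade-off:
apparent-age movement against the zero-order baseline is attainable, while
segmentation-grade cleanliness of the synthesized images — and with it the
scanline septum measurement — is generally not reached within the desk
budget. Which side of the trade-off a given short run lands on also varies
with the training seed: some seeds settle near the identity mapping (clean,
unconditioned), others in the conditioned-but-degraded regime. The
acceptance script reports both sides of this trade-off rather than hiding
either.

## Numerical choices and degenerate inputs

* Mapping bound: `tanh` (smooth) rather than a hard clip; the synthesized
  image is hard-clipped to `[0, 1]` with zero subgradient outside.
* Min-max rescaling of a constant image returns zeros (no 0/0).
* Geometry jitter violating `septum < LV radius` or the image frame is
  resampled up to 20 times, then errors.
* `sqrtm` eigenvalue clamp threshold `-1e-8`; PSNR of identical images is the
  `Inf` sentinel; septum scanlines use the central half of qualifying rows
  (oblique crossings near the cavity poles overestimate the radial width).
* Checkpoints carry parameters, optimizer moments, config, history and the
  RNG state; resumption reproduces the uninterrupted trajectory exactly
  (checkpoint granularity is the epoch).
* All randomness derives from one root seed through named streams
  (`derive_seed`), so runs are replayable end to end from the run manifest.

## Known limitations

* The critic's exact second-order path restricts it to piecewise-linear
  layers; swapping in attention or normalization would require a different
  penalty estimator.
* Phantom slopes are not calibrated to clinical effect sizes; only signs and
  rough magnitudes are meaningful.
* At desk scale the adversarial estimate is noisy; quantitative results in
  the test battery are monotonicity and improvement-over-baseline statements,
  not absolute error levels. Spatially localized covariate responses (and
  hence segmentation-based monotonicity of the septum of *synthesized*
  images) are not reliably attained within a single-CPU training budget.
* The 2-D, single-slice setting ignores through-plane aging effects.
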