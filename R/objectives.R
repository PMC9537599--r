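# WGAN-GP adversarial objective, cycle-consistency term, and their weighted
# total. The critic minimizes  E[D(x_gen, a_t)] - E[D(x_real, a)] +
# lambda_GP * E[(||grad_xhat D(xhat, a_t)|| - 1)^2]  on interpolates
# xhat = eps * x_real + (1 - eps) * x_gen; the generator minimizes
# -E[D(x_gen, a_t)] + lambda_cc * E[ |x - G(G(x, a_d), -a_d)| ].

#' Loss weights for the adversarial objective
#'
#' @param lambda_gp gradient-penalty factor (default 10).
#' @param lambda_cc cycle-consistency weight (default 1).
#' @return list with components `lambda_gp` and `lambda_cc`.
#' @export
loss_weights <- function(lambda_gp = 10, lambda_cc = 1) {
  stopifnot(lambda_gp >= 0, lambda_cc >= 0)
  list(lambda_gp = lambda_gp, lambda_cc = lambda_cc)
}

# Draw interpolates xhat = eps x_real + (1 - eps) x_gen, eps ~ U(0,1)
# independently per batch element.
interpolate_pairs <- function(x_real, x_gen, rng_seed) {
  stopifnot(all(dim(x_real) == dim(x_gen)))
  N <- dim(x_real)[4]
  eps <- with_seed(rng_seed, "gp_interpolation", runif(N))
  hw <- prod(dim(x_real)[1:3])
  e <- rep(eps, each = hw)
  list(xhat = array(e * x_real + (1 - e) * x_gen, dim(x_real)), eps = eps)
}

#' WGAN-GP gradient penalty
#'
#' Computes `mean((||grad_xhat D(xhat, a_t)||_2 - 1)^2)` over a batch, where
#' `xhat` lies on the segment between paired real and generated samples at an
#' independently drawn uniform position per element, and the norm runs over
#' all pixels of one sample.
#'
#' @param critic a [critic_net()].
#' @param x_real,x_gen arrays of identical shape (matrix, `(H,W,N)` or
#'   `(H,W,1,N)`).
#' @param a_t covariate presented to the critic (target covariate of the
#'   generated samples).
#' @param rng_seed seed for the interpolation draws.
#' @return scalar penalty.
#' @export
gradient_penalty <- function(critic, x_real, x_gen, a_t, rng_seed = 1L) {
  xr <- as_batch(x_real); xg <- as_batch(x_gen)
  ip <- interpolate_pairs(xr, xg, rng_seed)
  N <- dim(xr)[4]
  if (length(a_t) == 1L) a_t <- rep(a_t, N)
  fw <- critic_apply(critic, ip$xhat, a_t)
  critic_gp_chain(critic, fw$cache, scale = 0, accumulate = FALSE)
}

#' Critic (discriminator) loss
#'
#' The loss the critic minimizes under the WGAN-GP min-max objective:
#' `E[D(x_gen, a_t)] - E[D(x_real, a_real)] + lambda_GP * penalty`. Generated
#' samples are produced from the source batch with gap `a_t - a_s`; the real
#' term presents real images with their own true covariates.
#'
#' @param critic a [critic_net()].
#' @param generator a [generator_net()].
#' @param x_real_s source images (matrix or stack) with covariates `a_s`.
#' @param a_s source covariates.
#' @param a_t target covariates for the synthesized batch.
#' @param x_real_t independent real batch for the critic's real term.
#' @param a_real_t true covariates of `x_real_t`; defaults to `a_t`.
#' @param weights a [loss_weights()].
#' @param rng_seed seed for the gradient-penalty interpolation.
#' @return a `loss_report` list: `critic_core`, `gp`, `critic_total`, plus the
#'   weights used.
#' @export
critic_loss <- function(critic, generator, x_real_s, a_s, a_t,
                        x_real_t = x_real_s, a_real_t = NULL,
                        weights = loss_weights(), rng_seed = 1L) {
  xs <- as_batch(x_real_s); xt <- as_batch(x_real_t)
  if (dim(xs)[4] != dim(xt)[4]) stop("mismatched batch sizes")
  N <- dim(xs)[4]
  if (length(a_s) == 1L) a_s <- rep(a_s, N)
  if (length(a_t) == 1L) a_t <- rep(a_t, N)
  if (is.null(a_real_t)) a_real_t <- a_t
  gen <- generator_apply(generator, ad_const(xs), a_t - a_s)
  x_gen <- gen$output$v
  s_gen <- critic_apply(critic, x_gen, a_t)$score
  s_real <- critic_apply(critic, xt, a_real_t)$score
  core <- mean(s_gen) - mean(s_real)
  gp <- gradient_penalty(critic, xt, x_gen, a_t, rng_seed)
  structure(list(critic_core = core, gp = gp,
                 critic_total = core + weights$lambda_gp * gp,
                 lambda_gp = weights$lambda_gp, lambda_cc = weights$lambda_cc),
            class = "loss_report")
}

#' Cycle-consistency loss
#'
#' Mean absolute reconstruction error after a round trip through the
#' generator: `mean | x - G(G(x, a_d), -a_d) |`, averaged over batch and
#' pixels.
#'
#' @inheritParams generator_forward
#' @return scalar loss.
#' @export
cycle_loss <- function(generator, x, a_d) {
  xb <- as_batch(x)
  N <- dim(xb)[4]
  if (length(a_d) == 1L) a_d <- rep(a_d, N)
  fwd <- generator_apply(generator, ad_const(xb), a_d)
  back <- generator_apply(generator, fwd$output, -a_d)
  mean(abs(xb - back$output$v))
}

#' Generator loss
#'
#' The loss the generator minimizes: `-E[D(G(x, a_d), a_s + a_d)] +
#' lambda_cc * cycle_loss`.
#'
#' @inheritParams critic_loss
#' @param x source images; `a_d` covariate gaps.
#' @return a `loss_report` list with `generator_adv`, `cycle`,
#'   `generator_total` and the weights.
#' @export
generator_loss <- function(critic, generator, x, a_s, a_d,
                           weights = loss_weights()) {
  xb <- as_batch(x)
  N <- dim(xb)[4]
  if (length(a_s) == 1L) a_s <- rep(a_s, N)
  if (length(a_d) == 1L) a_d <- rep(a_d, N)
  fwd <- generator_apply(generator, ad_const(xb), a_d)
  adv <- -mean(critic_apply(critic, fwd$output$v, a_s + a_d)$score)
  back <- generator_apply(generator, fwd$output, -a_d)
  cyc <- mean(abs(xb - back$output$v))
  structure(list(generator_adv = adv, cycle = cyc,
                 generator_total = adv + weights$lambda_cc * cyc,
                 lambda_gp = weights$lambda_gp, lambda_cc = weights$lambda_cc),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  flds <- setdiff(names(x), c("lambda_gp", "lambda_cc"))
  cat("loss_report:", paste(sprintf("%s=%.4g", flds, unlist(x[flds])),
                            collapse = "  "), "\n")
  invisible(x)
}
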