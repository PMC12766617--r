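# Wasserstein adversarial losses with gradient penalty.
#
# critic_loss    = mean(critic(fake)) - mean(critic(real)) + penalty
# gen_adv_loss   = -mean(critic(fake))
# penalty        = lambda_gp * mean((||grad_x critic(x~)||_2 - 1)^2)
# on per-sample random convex interpolates x~ between real and fake; the
# critic score of a sample is the mean of its patch score grid.

#' Wasserstein-GP loss terms for one batch
#'
#' @param disc a \code{discriminator}.
#' @param real_batch,fake_batch lists of (H, W, C) arrays of equal length and
#'   shape.
#' @param lambda_gp gradient-penalty coefficient (>= 0).
#' @param seed seed for the interpolation draws.
#' @return List: \code{critic_loss}, \code{generator_adv_loss},
#'   \code{penalty}, plus per-sample interpolate gradient norms
#'   \code{grad_norms}.
#' @export
wgan_gp_losses <- function(disc, real_batch, fake_batch, lambda_gp = 10, seed = NULL) {
  stop_if_not(lambda_gp >= 0, "lambda_gp must be non-negative")
  stop_if_not(length(real_batch) == length(fake_batch) && length(real_batch) > 0,
              "real and fake batches must have matching nonzero length")
  n <- length(real_batch)
  s_real <- vapply(real_batch, function(x) mean(discriminator_forward(disc, x)$y), 0)
  s_fake <- vapply(fake_batch, function(x) mean(discriminator_forward(disc, x)$y), 0)
  eps <- with_seed(seed, stats::runif(n))
  norms <- numeric(n)
  for (i in seq_len(n)) {
    stop_if_not(identical(dim(real_batch[[i]]), dim(fake_batch[[i]])),
                "real/fake shape mismatch")
    xt <- eps[i] * real_batch[[i]] + (1 - eps[i]) * fake_batch[[i]]
    norms[i] <- sqrt(sum(critic_score_and_input_grad(disc, xt)$dx^2))
  }
  penalty <- lambda_gp * mean((norms - 1)^2)
  list(critic_loss = mean(s_fake) - mean(s_real) + penalty,
       generator_adv_loss = -mean(s_fake),
       penalty = penalty, grad_norms = norms)
}

# Parameter gradients of the full critic objective on one batch.
#
# The gradient-penalty term needs d/dtheta of an input-gradient norm (a
# second derivative). With v_i = (2/n) lambda_gp (||g_i|| - 1) g_i / ||g_i||
# held fixed, d penalty/d theta = d/d theta sum_i v_i . grad_x D(x~_i), which
# is the theta-gradient of a directional derivative; it is evaluated by a
# central finite difference of grad_theta D along v_i. The critic is
# piecewise linear (convolutions + leaky ReLU), so away from activation
# kinks the finite difference is exact.
critic_grads <- function(disc, real_batch, fake_batch, lambda_gp, seed = NULL,
                         fd_eps = 1e-4) {
  n <- length(real_batch)
  grads <- lapply(disc$params, function(x) x * 0)
  acc <- function(g, scale) for (nm in names(g)) grads[[nm]] <<- grads[[nm]] + scale * g[[nm]]
  score_param_grads <- function(x) {
    fw <- discriminator_forward(disc, x)
    dy <- array(1 / length(fw$y), dim(fw$y))
    discriminator_backward(disc, fw$cache, dy)$grads
  }
  for (i in seq_len(n)) {
    acc(score_param_grads(fake_batch[[i]]), 1 / n)
    acc(score_param_grads(real_batch[[i]]), -1 / n)
  }
  loss_terms <- wgan_gp_losses(disc, real_batch, fake_batch, lambda_gp, seed)
  if (lambda_gp > 0) {
    eps <- with_seed(seed, stats::runif(n))
    for (i in seq_len(n)) {
      xt <- eps[i] * real_batch[[i]] + (1 - eps[i]) * fake_batch[[i]]
      g <- critic_score_and_input_grad(disc, xt)$dx
      nrm <- sqrt(sum(g^2))
      if (nrm < 1e-12) next
      v <- (2 / n) * lambda_gp * (nrm - 1) * g / nrm
      vn <- sqrt(sum(v^2))
      if (vn < 1e-14) next
      h <- fd_eps / vn
      gp <- score_param_grads(xt + h * v)
      gm <- score_param_grads(xt - h * v)
      for (nm in names(gp)) grads[[nm]] <- grads[[nm]] + (gp[[nm]] - gm[[nm]]) / (2 * h)
    }
  }
  list(grads = grads, losses = loss_terms)
}
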