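# De-noising pipeline: adversarial losses, augmentation, patient splits,
# training dynamics and ensembling.

test_that("gradient penalty is analytic for an effectively linear critic", {
  # leaky-ReLU slope 1 makes the critic an affine map, so the input gradient
  # of its mean patch score is constant and the penalty has a closed form
  set.seed(201)
  disc <- build_discriminator(fd_disc_config(slope = 1), seed = 11)
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  g <- cdtidenoise:::critic_score_and_input_grad(disc, x)$dx
  nrm <- sqrt(sum(g^2))
  # rescale the output stage so the gradient norm is exactly 1
  disc$params[["out.W"]] <- disc$params[["out.W"]] / nrm
  disc$params[["out.b"]] <- disc$params[["out.b"]] / nrm
  real <- list(array(rnorm(16 * 16 * 6), c(16, 16, 6)))
  fake <- list(array(rnorm(16 * 16 * 6), c(16, 16, 6)))
  l1 <- wgan_gp_losses(disc, real, fake, lambda_gp = 10, seed = 1)
  expect_lt(l1$penalty, 1e-12)
  # gradient norm 2 -> penalty = lambda_gp * (2 - 1)^2
  disc$params[["out.W"]] <- disc$params[["out.W"]] * 2
  disc$params[["out.b"]] <- disc$params[["out.b"]] * 2
  l2 <- wgan_gp_losses(disc, real, fake, lambda_gp = 10, seed = 1)
  expect_equal(l2$penalty, 10, tolerance = 1e-8)
  expect_gte(l2$penalty, 0)
  # loss identities
  expect_equal(l2$critic_loss - l2$penalty, -l2$generator_adv_loss -
                 mean(vapply(real, function(r)
                   mean(discriminator_forward(disc, r)$y), 0)),
               tolerance = 1e-10)
  expect_error(wgan_gp_losses(disc, real, fake, lambda_gp = -1),
               "non-negative")
})

test_that("rotation augmentation reorients tensors correctly", {
  ph <- small_phantom()
  pair0 <- augment_sample(ph$tensor, ph$tensor, ph$geometry$myo_mask,
                          angle_deg = 0, crop_spec = NULL)
  expect_identical(pair0$noisy$d, ph$tensor$d)    # bitwise identity
  # 90-degree conjugation oracle: D' = R D R^T with R the quarter-turn
  tf90 <- rotate_tensor_field(ph$tensor, 90)
  n <- nrow(ph$tensor$d)
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)   # x' = -y, y' = x
  idx <- which(ph$geometry$myo_mask, arr.ind = TRUE)[1:8, ]
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    d6 <- ph$tensor$d[i, j, ]
    D <- matrix(c(d6[1], d6[4], d6[5], d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3, 3)
    Dp <- R %*% D %*% t(R)
    # voxel (i, j) maps to (j, n + 1 - i) under the quarter turn
    got <- tf90$d[j, n + 1 - i, ]
    expect_equal(got, c(Dp[1, 1], Dp[2, 2], Dp[3, 3], Dp[1, 2], Dp[1, 3],
                        Dp[2, 3]), tolerance = 1e-12)
  }
  # Dxx/Dyy swap and in-plane cross-term sign flip, in aggregate
  expect_equal(sort(as.vector(tf90$d[, , 1])), sort(as.vector(ph$tensor$d[, , 2])))
  expect_equal(sort(as.vector(tf90$d[, , 4])), sort(as.vector(-ph$tensor$d[, , 4])))
})

test_that("content-aware crops always contain the myocardium", {
  for (seed in 1:5) {
    ph <- phantom_cohort(1, c(64, 64), seed = seed)[[1]]
    out <- augment_sample(ph$tensor, ph$tensor, ph$geometry$myo_mask,
                          angle_deg = c(0, 37, 90, 180, 241)[seed],
                          crop_spec = list(size = c(48, 48)), seed = seed)
    expect_equal(dim(out$noisy$d), c(48, 48, 6))
    expect_equal(sum(out$mask), sum(rotate_tensor_field(
      tensor_field(ph$tensor$d, ph$geometry$myo_mask),
      c(0, 37, 90, 180, 241)[seed])$mask))
  }
  ph <- small_phantom()
  expect_error(augment_sample(ph$tensor, ph$tensor, ph$geometry$myo_mask,
                              crop_spec = list(size = c(8, 8))),
               "does not fit")
})

test_that("patient-level splitting is disjoint, sized 80:10:10 and seeded", {
  ids <- sprintf("p%02d", 1:10)
  sp <- split_patients(ids, seed = 5)
  expect_equal(lengths(sp), c(train = 8, val = 1, test = 1))
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(unlist(sp), ids)
  expect_identical(sp, split_patients(ids, seed = 5))
  expect_false(identical(sp, split_patients(ids, seed = 6)))
  expect_error(split_patients(ids[1:9]), "at least 10")
})

test_that("a tiny generator overfits a single pair by MAE regression", {
  set.seed(202)
  cfg <- fd_gen_config()
  x <- array(rnorm(16 * 16 * 6, sd = 0.5), c(16, 16, 6))
  # target = input plus a smooth spatial correction (the residual branch's
  # native regime)
  g <- outer(sin(seq(0, pi, length.out = 16)), cos(seq(0, pi, length.out = 16)))
  y <- x + array(rep(g, 6), c(16, 16, 6)) * 0.15
  pair <- list(list(x = x, y = y, mask = matrix(TRUE, 16, 16)))
  tcfg <- train_config(lr = 1e-2, epochs = 400, batch_size = 1,
                       lambda_adv = 0, seed = 9)
  ck <- train_denoiser(pair, pair, cfg, tcfg)
  h <- ck$history
  # identity at init + lambda_adv = 0: the first logged loss is the raw MAE
  expect_equal(h$train_mae[1], mean(abs(x - y)), tolerance = 1e-12)
  expect_lt(tail(h$train_mae, 1), 0.1 * h$train_mae[1])
  # checkpoint selection takes the epoch with minimal validation loss
  expect_equal(ck$best_val, min(h$val_mae))
  expect_equal(h$val_mae[ck$best_epoch], min(h$val_mae))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(203)
  pairs <- lapply(1:3, function(i) {
    x <- array(rnorm(16 * 16 * 6, sd = 0.3), c(16, 16, 6))
    list(x = x, y = x * 0.5, mask = matrix(TRUE, 16, 16))
  })
  tcfg <- train_config(lr = 1e-3, epochs = 3, batch_size = 2,
                       lambda_adv = 0, seed = 31, augment_rot90 = TRUE)
  a <- train_denoiser(pairs, pairs[1], fd_gen_config(), tcfg)
  b <- train_denoiser(pairs, pairs[1], fd_gen_config(), tcfg)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("adversarial training runs and stays finite at tiny scale", {
  set.seed(204)
  pairs <- lapply(1:2, function(i) {
    x <- array(rnorm(16 * 16 * 6, sd = 0.3), c(16, 16, 6))
    list(x = x, y = x * 0.5, mask = matrix(TRUE, 16, 16))
  })
  tcfg <- train_config(lr = 1e-3, epochs = 2, batch_size = 2,
                       lambda_adv = 0.01, lambda_gp = 10, critic_steps = 1,
                       seed = 41, disc = fd_disc_config())
  ck <- train_denoiser(pairs, pairs[1], fd_gen_config(), tcfg)
  expect_true(all(is.finite(ck$history$train_mae)))
  expect_true(all(is.finite(ck$history$val_mae)))
})

test_that("ensemble averaging obeys its algebraic contracts", {
  cfg <- fd_gen_config()
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  mk_ck <- function(bias) {
    gen <- build_generator(cfg, seed = 55)
    gen$params[["out_conv.b"]][] <- bias
    structure(list(params = gen$params, config = cfg,
                   history = data.frame(), best_epoch = 0L, best_val = 0),
              class = "gen_checkpoint")
  }
  # identical members reduce to a single member
  same <- list(mk_ck(0.05), mk_ck(0.05))
  expect_equal(ensemble_predict(same, x),
               generator_predict(checkpoint_generator(same[[1]]), x))
  # members predicting truth + e and truth - e cancel exactly
  pm <- list(mk_ck(0.2), mk_ck(-0.2))
  expect_equal(ensemble_predict(pm, x), x, tolerance = 1e-12)
  # convexity: ensemble MAE never exceeds the mean member MAE
  set.seed(205)
  rand_members <- lapply(1:3, function(i) {
    gen <- build_generator(cfg, seed = 60 + i)
    gen$params[["out_conv.W"]][] <- rnorm(length(gen$params[["out_conv.W"]]), 0, 0.1)
    structure(list(params = gen$params, config = cfg,
                   history = data.frame(), best_epoch = 0L, best_val = 0),
              class = "gen_checkpoint")
  })
  for (rep in 1:3) {
    xb <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
    target <- xb * 0.8
    preds <- lapply(rand_members, function(m)
      generator_predict(checkpoint_generator(m), xb))
    ens <- ensemble_predict(rand_members, xb)
    mae_ens <- mean(abs(ens - target))
    mae_mean <- mean(vapply(preds, function(p) mean(abs(p - target)), 0))
    expect_lte(mae_ens, mae_mean + 1e-12)
  }
  # inconsistent configurations are rejected
  other <- mk_ck(0)
  other$config$base_width <- 8
  expect_error(ensemble_predict(list(mk_ck(0), other), x), "inconsistent")
})
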