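# Training loop for the tensor-to-tensor de-noiser: mean-absolute-error
# regression with an optional Wasserstein-GP adversarial term, AdamW
# optimization, per-epoch validation and lowest-validation-loss checkpoint
# selection. Fully seeded.

#' Training configuration
#'
#' Defaults follow the full-scale recipe (AdamW, learning rate 1e-4,
#' beta1 0.9, beta2 0.999, zero weight decay, 500 epochs, batch size 8,
#' MAE + lambda_adv * adversarial loss); epochs, batch size and learning
#' rate are overridable for desk-scale presets.
#'
#' @param lr learning rate.
#' @param beta1,beta2 AdamW moment decays.
#' @param weight_decay decoupled weight decay.
#' @param epochs training epochs.
#' @param batch_size samples per update.
#' @param lambda_adv adversarial loss weight (0 disables the critic).
#' @param lambda_gp gradient-penalty coefficient.
#' @param critic_steps critic updates per generator update.
#' @param seed master seed (initialization, shuffling, augmentation draws).
#' @param augment_rot90 apply a random exact 90-degree rotation (with tensor
#'   reorientation) to each training sample when batched.
#' @param disc a \code{disc_config} for the critic (when lambda_adv > 0).
#' @param verbose print per-epoch losses to stderr.
#' @return Class \code{train_config}.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 0, epochs = 500, batch_size = 8,
                         lambda_adv = 0.01, lambda_gp = 10, critic_steps = 1,
                         seed = 1, augment_rot90 = FALSE,
                         disc = disc_config(), verbose = FALSE) {
  stop_if_not(lr > 0 && epochs >= 1 && batch_size >= 1, "invalid optimizer settings")
  stop_if_not(lambda_adv >= 0 && lambda_gp >= 0 && critic_steps >= 1,
              "adversarial settings must be non-negative")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, epochs = epochs,
                 batch_size = batch_size, lambda_adv = lambda_adv,
                 lambda_gp = lambda_gp, critic_steps = critic_steps,
                 seed = seed, augment_rot90 = isTRUE(augment_rot90),
                 disc = disc, verbose = isTRUE(verbose)),
            class = "train_config")
}

# random exact 90-degree rotation of a normalized (x, y, mask) pair;
# draws from the current RNG stream
rot90_pair <- function(pair) {
  k <- sample(0:3, 1)
  if (k == 0) return(pair)
  rot_arr <- function(a) {
    ch <- lapply(seq_len(dim(a)[3]), function(j) {
      m <- a[, , j]
      for (r in seq_len(k)) m <- rot90_mat(m)
      m
    })
    arr <- array(unlist(ch), c(dim(ch[[1]]), length(ch)))
    array(reorient_rows(matrix(arr, ncol = 6), 90 * k), dim(arr))
  }
  mk <- pair$mask
  for (r in seq_len(k)) mk <- rot90_mat(mk)
  list(x = rot_arr(pair$x), y = rot_arr(pair$y), mask = mk)
}

mae_loss <- function(pred, target) mean(abs(pred - target))

#' Train a tensor de-noising generator
#'
#' Alternates critic and generator updates (supervised MAE regression when
#' \code{lambda_adv = 0}), logs per-epoch training and validation MAE, and
#' returns the parameters of the epoch with the lowest validation loss.
#' The per-epoch training loss is evaluated at the pre-update forward pass,
#' so with an identity-initialized generator the first logged loss equals
#' the raw input/target MAE.
#'
#' @param pairs training list; each element has \code{x} and \code{y}
#'   (H, W, 6) normalized arrays and a logical \code{mask}.
#' @param val_pairs validation list in the same format (nonempty).
#' @param config a \code{gen_config}.
#' @param tcfg a \code{train_config}.
#' @return Class \code{gen_checkpoint}: best \code{params}, \code{config},
#'   \code{history} data frame (epoch, train_mae, val_mae), \code{best_epoch}
#'   and \code{best_val}.
#' @export
train_denoiser <- function(pairs, val_pairs, config, tcfg = train_config()) {
  stopifnot(inherits(config, "gen_config"), inherits(tcfg, "train_config"))
  stop_if_not(length(pairs) > 0 && length(val_pairs) > 0,
              "train and validation sets must be nonempty")
  with_seed(tcfg$seed, {
    gen <- build_generator(config)
    gstate <- adam_init(gen$params)
    use_adv <- tcfg$lambda_adv > 0
    if (use_adv) {
      disc <- build_discriminator(tcfg$disc)
      dstate <- adam_init(disc$params)
    }
    history <- data.frame(epoch = integer(), train_mae = numeric(),
                          val_mae = numeric())
    best_val <- Inf; best_params <- gen$params; best_epoch <- 0L

    val_mae <- function() {
      mean(vapply(val_pairs, function(pr)
        mae_loss(generator_forward(gen, pr$x)$y, pr$y), 0))
    }

    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(length(pairs))
      ep_losses <- c()
      for (b0 in seq(1, length(ord), by = tcfg$batch_size)) {
        bi <- ord[b0:min(b0 + tcfg$batch_size - 1, length(ord))]
        batch <- lapply(pairs[bi], function(pr)
          if (tcfg$augment_rot90) rot90_pair(pr) else pr)
        fw <- lapply(batch, function(pr) generator_forward(gen, pr$x))
        fakes <- lapply(fw, `[[`, "y")
        reals <- lapply(batch, `[[`, "y")
        batch_mae <- mean(mapply(function(f, pr) mae_loss(f, pr$y), fakes, batch))
        if (!is.finite(batch_mae))
          stop(sprintf("training diverged at epoch %d (non-finite loss)", ep),
               call. = FALSE)
        ep_losses <- c(ep_losses, batch_mae)

        if (use_adv) {
          for (cs in seq_len(tcfg$critic_steps)) {
            cg <- critic_grads(disc, reals, fakes, tcfg$lambda_gp)
            st <- adam_step(disc$params, cg$grads, dstate, tcfg$lr,
                            tcfg$beta1, tcfg$beta2,
                            weight_decay = tcfg$weight_decay)
            disc$params <- st$params; dstate <- st$state
          }
        }
        gacc <- NULL
        nb <- length(batch)
        for (i in seq_len(nb)) {
          dy <- sign(fw[[i]]$y - batch[[i]]$y) / (length(fw[[i]]$y) * nb)
          if (use_adv) {
            gadv <- critic_score_and_input_grad(disc, fakes[[i]])$dx
            dy <- dy - tcfg$lambda_adv * gadv / nb
          }
          gr <- generator_backward(gen, fw[[i]]$cache, dy)$grads
          gacc <- if (is.null(gacc)) gr
                  else mapply(`+`, gacc, gr, SIMPLIFY = FALSE)
        }
        st <- adam_step(gen$params, gacc, gstate, tcfg$lr, tcfg$beta1,
                        tcfg$beta2, weight_decay = tcfg$weight_decay)
        gen$params <- st$params; gstate <- st$state
      }
      vm <- val_mae()
      if (!is.finite(vm))
        stop(sprintf("training diverged at epoch %d (non-finite validation loss)", ep),
             call. = FALSE)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_mae = mean(ep_losses),
                                           val_mae = vm))
      if (vm < best_val) {
        best_val <- vm; best_params <- gen$params; best_epoch <- ep
      }
      if (tcfg$verbose)
        message(sprintf("epoch %3d  train MAE %.5f  val MAE %.5f", ep,
                        mean(ep_losses), vm))
    }
    structure(list(params = best_params, config = config, history = history,
                   best_epoch = best_epoch, best_val = best_val,
                   train_config = tcfg),
              class = "gen_checkpoint")
  })
}

#' Load a checkpoint as a usable generator
#'
#' @param ckpt a \code{gen_checkpoint}.
#' @return A \code{generator}.
#' @export
checkpoint_generator <- function(ckpt) {
  stopifnot(inherits(ckpt, "gen_checkpoint"))
  structure(list(params = ckpt$params, config = ckpt$config), class = "generator")
}
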