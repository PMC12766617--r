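# Bagging ensemble of independently initialized and trained de-noisers;
# predictions are averaged elementwise in normalized tensor space.

#' Ensemble specification
#'
#' @param n_members ensemble size (default 5, the full-scale choice).
#' @param member_seeds distinct training seeds, one per member.
#' @return Class \code{ensemble_spec}.
#' @export
ensemble_spec <- function(n_members = 5, member_seeds = seq_len(n_members)) {
  stop_if_not(n_members >= 1, "need at least one ensemble member")
  stop_if_not(length(member_seeds) == n_members && !anyDuplicated(member_seeds),
              "member seeds must be distinct, one per member")
  structure(list(n_members = n_members, member_seeds = member_seeds),
            class = "ensemble_spec")
}

#' Train a de-noising ensemble
#'
#' Trains \code{n_members} generators with identical architecture and data
#' but distinct seeds (independent initialization, shuffling and
#' augmentation draws).
#'
#' @param pairs,val_pairs training/validation pairs
#'   (see \code{\link{train_denoiser}}).
#' @param config a \code{gen_config} shared by all members.
#' @param tcfg a \code{train_config}; its seed is replaced per member.
#' @param spec an \code{ensemble_spec}.
#' @param norm the \code{norm_spec} the pairs were normalized with (stored
#'   for later de-noising of physical tensor fields).
#' @return Class \code{denoise_ensemble}: member checkpoints, shared config,
#'   the normalization spec and the ensemble spec.
#' @export
train_ensemble <- function(pairs, val_pairs, config, tcfg, spec = ensemble_spec(),
                           norm = NULL) {
  members <- lapply(spec$member_seeds, function(s) {
    tc <- tcfg; tc$seed <- s
    train_denoiser(pairs, val_pairs, config, tc)
  })
  structure(list(members = members, config = config, norm = norm, spec = spec),
            class = "denoise_ensemble")
}

#' Ensemble prediction on a normalized tensor grid
#'
#' Elementwise mean of the member outputs.
#'
#' @param ensemble a \code{denoise_ensemble} (or list of
#'   \code{gen_checkpoint}s).
#' @param x (H, W, 6) normalized array.
#' @return (H, W, 6) de-noised normalized array.
#' @export
ensemble_predict <- function(ensemble, x) {
  members <- if (inherits(ensemble, "denoise_ensemble")) ensemble$members else ensemble
  stop_if_not(length(members) >= 1, "ensemble has no members")
  cfg0 <- members[[1]]$config
  for (m in members)
    stop_if_not(identical(unclass(m$config), unclass(cfg0)),
                "ensemble members have inconsistent configurations")
  out <- NULL
  for (m in members) {
    y <- generator_forward(checkpoint_generator(m), x)$y
    out <- if (is.null(out)) y else out + y
  }
  out / length(members)
}

#' De-noise a physical tensor field with a trained ensemble
#'
#' Normalizes the field with the ensemble's stored spec, averages the member
#' predictions and denormalizes back to mm^2/s.
#'
#' @param ensemble a \code{denoise_ensemble} carrying a \code{norm} spec.
#' @param tf a \code{tensor_field} (e.g. a noisy LLS fit).
#' @return A de-noised \code{tensor_field} on the same mask.
#' @export
denoise_tensor_field <- function(ensemble, tf) {
  stopifnot(inherits(ensemble, "denoise_ensemble"), inherits(tf, "tensor_field"))
  stop_if_not(!is.null(ensemble$norm), "ensemble carries no normalization spec")
  x <- normalize_tensor(tf, ensemble$norm)
  y <- ensemble_predict(ensemble, x)
  denormalize_tensor(y, ensemble$norm, tf$mask)
}
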