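# Protocol-time arithmetic and the seeded end-to-end experiment engines that
# tie phantom generation, DWI simulation, tensor fitting, de-noising and
# evaluation into the full pipeline.

#' Scan-time arithmetic
#'
#' Total acquisition time as the product of minutes per slice per cardiac
#' phase, number of phases and number of slices. With the standard STEAM
#' protocol (about 8 min per slice at one phase), two phases give 16 min per
#' slice and whole-heart coverage at 12 slices gives 192 min.
#'
#' @param minutes_per_slice_per_phase,n_phases,n_slices non-negative numbers.
#' @return Total minutes.
#' @export
scan_time_minutes <- function(minutes_per_slice_per_phase, n_phases, n_slices) {
  stop_if_not(minutes_per_slice_per_phase >= 0 && n_phases >= 0 && n_slices >= 0,
              "scan-time inputs must be non-negative")
  minutes_per_slice_per_phase * n_phases * n_slices
}

#' Repetition duration in heartbeats (and seconds)
#'
#' One STEAM repetition (one b0 image plus 6 DWIs, including preparation
#' pulses) spans 18 heartbeats.
#'
#' @param n_repetitions repetition count (>= 0).
#' @param bpm optional heart rate; when given, seconds are also returned.
#' @return List: \code{heartbeats}, and \code{seconds} when \code{bpm} given.
#' @export
repetition_heartbeats <- function(n_repetitions, bpm = NULL) {
  stop_if_not(n_repetitions >= 0, "repetition count must be non-negative")
  hb <- 18 * n_repetitions
  out <- list(heartbeats = hb)
  if (!is.null(bpm)) {
    stop_if_not(bpm > 0, "heart rate must be positive")
    out$seconds <- hb * 60 / bpm
  }
  out
}

# simulate one subject's full acquisition and fit the reference plus the
# reduced-regime tensors for the requested repetition-subset positions
prepare_subject <- function(ph, sigma, seed, regime = "1BH",
                            positions = "first") {
  ser <- simulate_dwi(ph$tensor, ph$s0, make_protocol("full"), sigma, seed)
  mask <- ph$geometry$myo_mask
  avg_full <- average_repetitions(ser)
  ref <- fit_lls(avg_full, build_design_matrix(avg_full), mask)
  noisy <- lapply(stats::setNames(positions, positions), function(pos) {
    sub <- regime_subset(ser, regime, pos)
    avg <- average_repetitions(sub)
    fit_lls(avg, build_design_matrix(avg), mask)
  })
  list(phantom = ph, reference = ref, noisy = noisy, mask = mask,
       frame = ph$orientation$frame)
}

#' Noise-induced FA inflation across breath-hold regimes
#'
#' Over seeded phantom replicates, fits tensors from the first-repetition
#' subsets of the 5BH, 3BH and 1BH regimes and measures the FA mean absolute
#' error against the analytic ground truth. Fewer repetitions mean lower SNR
#' after averaging, so the FA error is expected to grow as breath-holds
#' decrease (the classic noise-driven FA inflation).
#'
#' @param n_replicates phantom replicates.
#' @param snr b0-image signal-to-noise ratio S0/sigma.
#' @param grid_shape phantom grid.
#' @param seed master seed.
#' @return List: per-replicate data frame \code{errors} (replicate, regime,
#'   fa_mae) and named \code{medians} for 5BH/3BH/1BH.
#' @export
noise_bias_study <- function(n_replicates = 20, snr = 25,
                             grid_shape = c(64, 64), seed = 1) {
  sigma <- 1 / snr
  cohort <- phantom_cohort(n_replicates, grid_shape, seed = seed %% 2147483647)
  regimes <- c("5BH", "3BH", "1BH")
  rows <- list()
  for (i in seq_len(n_replicates)) {
    ph <- cohort[[i]]
    ser <- simulate_dwi(ph$tensor, ph$s0, make_protocol("full"), sigma,
                        seed = (seed * 1000 + i) %% 2147483647)
    mask <- ph$geometry$myo_mask
    for (rg in regimes) {
      sub <- regime_subset(ser, rg, "first")
      avg <- average_repetitions(sub)
      fit <- fit_lls(avg, build_design_matrix(avg), mask)
      fa <- compute_md_fa(eigendecompose(fit$tensor))$fa
      rows[[length(rows) + 1]] <- data.frame(
        replicate = i, regime = rg,
        fa_mae = mean(abs(fa[mask] - ph$truth$fa[mask]), na.rm = TRUE))
    }
  }
  errors <- do.call(rbind, rows)
  medians <- vapply(regimes, function(rg)
    stats::median(errors$fa_mae[errors$regime == rg]), 0)
  list(errors = errors, medians = medians)
}

#' Desk-scale de-noising study configuration
#'
#' Conditions of the synthetic end-to-end experiment: cohort sizes, grid,
#' regime, SNR, the tiny generator preset and the short training schedule
#' used at desk scale (learning rate raised to 1e-3 and a few epochs, the
#' preset's own schedule for small networks and few samples).
#'
#' @param n_train_subjects cohort that is split 80:10:10 into
#'   train/val/test at the patient level.
#' @param n_eval_subjects independent held-out evaluation cohort.
#' @param n_sit_subjects mirrored-chirality out-of-distribution subjects.
#' @param grid_shape phantom grid.
#' @param regime reduced breath-hold regime under study.
#' @param snr b0 signal-to-noise ratio.
#' @param members ensemble size at desk scale.
#' @param epochs,batch_size,lr desk-scale training schedule.
#' @param lambda_adv adversarial weight (0 = pure MAE regression).
#' @param augment_rot90 random exact-rotation augmentation during training.
#' @return List of study settings.
#' @export
denoise_study_config <- function(n_train_subjects = 50, n_eval_subjects = 12,
                                 n_sit_subjects = 3, grid_shape = c(64, 64),
                                 regime = "1BH", snr = 25, members = 2,
                                 epochs = 8, batch_size = 4, lr = 3e-3,
                                 lambda_adv = 0, augment_rot90 = TRUE,
                                 crop_size = 48) {
  list(n_train_subjects = n_train_subjects, n_eval_subjects = n_eval_subjects,
       n_sit_subjects = n_sit_subjects, grid_shape = grid_shape,
       regime = regime, snr = snr, members = members, epochs = epochs,
       batch_size = batch_size, lr = lr, lambda_adv = lambda_adv,
       augment_rot90 = augment_rot90, crop_size = crop_size)
}

# evaluate one prepared subject: reference maps vs LLS maps vs (optionally)
# de-noised maps; errors against the full-repetition reference maps
eval_subject <- function(prep, ensemble = NULL) {
  fr <- prep$frame
  ref_maps <- cdti_maps(prep$reference$tensor, fr)
  lls_maps <- cdti_maps(prep$noisy[["first"]]$tensor, fr)
  out <- list(lls = map_errors(lls_maps, ref_maps, prep$mask))
  if (!is.null(ensemble)) {
    den <- denoise_tensor_field(ensemble, prep$noisy[["first"]]$tensor)
    out$denoised <- map_errors(cdti_maps(den, fr), ref_maps, prep$mask)
  }
  out
}

#' End-to-end synthetic de-noising study
#'
#' Runs the full pipeline at desk scale: generates a training cohort, splits
#' it at the patient level (80:10:10), simulates full acquisitions, fits
#' reference (all repetitions) and reduced-regime (first/central/last
#' repetition subsets) tensors, trains a bagging ensemble of tiny
#' windowed-attention de-noisers on the normalized tensor pairs, and
#' evaluates LLS vs de-noised map errors against the full-repetition
#' reference maps on an independent held-out cohort plus mirrored-chirality
#' (situs inversus) subjects.
#'
#' @param seed master seed driving every stage.
#' @param config settings from \code{\link{denoise_study_config}}.
#' @return List: per-subject error tables \code{lls_errors} and
#'   \code{dl_errors}, cohort medians, relative error reductions
#'   (percent), the SIT helix-angle error ratio, and the trained
#'   \code{ensemble}.
#' @export
run_denoise_study <- function(seed = 1, config = denoise_study_config()) {
  sigma <- 1 / config$snr
  base <- seed %% 100000
  positions <- c("first", "central", "last")

  cohort <- phantom_cohort(config$n_train_subjects, config$grid_shape,
                           seed = base * 7 + 1)
  sp <- split_patients(names(cohort), seed = base * 7 + 2)
  norm <- norm_spec("scale")

  make_pairs <- function(ids, pos) {
    pairs <- list()
    for (id in ids) {
      i <- match(id, names(cohort))
      prep <- prepare_subject(cohort[[id]], sigma, seed = base * 1000 + i,
                              regime = config$regime, positions = pos)
      crop <- if (is.null(config$crop_size)) NULL
              else list(size = rep(config$crop_size, 2))
      for (p in pos) {
        aug <- augment_sample(prep$noisy[[p]]$tensor, prep$reference$tensor,
                              prep$mask, angle_deg = 0, crop_spec = crop,
                              seed = base * 1000 + i)
        pairs[[length(pairs) + 1]] <- list(
          x = normalize_tensor(aug$noisy, norm),
          y = normalize_tensor(aug$target, norm), mask = aug$mask)
      }
    }
    pairs
  }
  train_pairs <- make_pairs(sp$train, positions)
  val_pairs <- make_pairs(sp$val, "first")

  gcfg <- gen_preset("tiny")
  tcfg <- train_config(lr = config$lr, epochs = config$epochs,
                       batch_size = config$batch_size,
                       lambda_adv = config$lambda_adv,
                       augment_rot90 = config$augment_rot90)
  es <- ensemble_spec(config$members,
                      member_seeds = base * 100 + seq_len(config$members))
  ensemble <- train_ensemble(train_pairs, val_pairs, gcfg, tcfg, es, norm = norm)

  eval_cohort <- function(n, cohort_seed, sit = FALSE) {
    ph_list <- phantom_cohort(n, config$grid_shape, seed = cohort_seed, sit = sit)
    lls <- list(); dl <- list()
    for (i in seq_along(ph_list)) {
      prep <- prepare_subject(ph_list[[i]], sigma,
                              seed = (base * 1000 + 500 + i + sit * 10000) %% 2147483647,
                              regime = config$regime, positions = "first")
      ev <- eval_subject(prep, ensemble)
      lls[[i]] <- ev$lls; dl[[i]] <- ev$denoised
    }
    list(lls = do.call(rbind, lls), dl = do.call(rbind, dl))
  }
  evn <- eval_cohort(config$n_eval_subjects, base * 7 + 3)
  evs <- eval_cohort(config$n_sit_subjects, base * 7 + 4, sit = TRUE)

  med <- function(df) vapply(df, stats::median, 0)
  m_lls <- med(evn$lls); m_dl <- med(evn$dl)
  reduction <- 100 * (m_lls - m_dl) / m_lls
  sit_ratio <- stats::median(evs$dl$ha_maae) / stats::median(evn$dl$ha_maae)

  list(lls_errors = evn$lls, dl_errors = evn$dl,
       sit_lls_errors = evs$lls, sit_dl_errors = evs$dl,
       medians = list(lls = m_lls, denoised = m_dl),
       reduction_pct = reduction, sit_ha_ratio = sit_ratio,
       ensemble = ensemble, split = sp, config = config, seed = seed)
}

#' Infarct-contrast study on a noiseless phantom
#'
#' Builds an infarcted phantom (elevated lesion MD against remote
#' myocardium), recomputes the MD map from the tensor field and measures the
#' infarct-remote contrast.
#'
#' @param md_lesion,md_remote prescribed mean diffusivities, mm^2/s.
#' @param fa_lesion,fa_remote prescribed anisotropies.
#' @param grid_shape phantom grid.
#' @return List: \code{delta_md} (mm^2/s), the lesion/remote mean MD, and
#'   the masks.
#' @export
infarct_contrast_study <- function(md_lesion = 1.25e-3, md_remote = 1.05e-3,
                                   fa_lesion = 0.25, fa_remote = 0.45,
                                   grid_shape = c(64, 64)) {
  ph <- lv_phantom(grid_shape = grid_shape, md = md_remote, fa = fa_remote)
  les <- lesion_spec(theta_start_deg = 0, theta_width_deg = 100,
                     md_lesion = md_lesion, fa_lesion = fa_lesion)
  inf <- add_infarct(ph$tensor, ph$geometry, les)
  md_map <- compute_md_fa(eigendecompose(inf$field))$md
  list(delta_md = delta_md(md_map, inf$lesion_mask, inf$remote_mask),
       md_lesion_mean = mean(md_map[inf$lesion_mask]),
       md_remote_mean = mean(md_map[inf$remote_mask]),
       lesion_mask = inf$lesion_mask, remote_mask = inf$remote_mask)
}
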