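# Clinical-validation analyses: transmural helix-angle profiles, three-zone
# fractional-anisotropy distribution, and infarct-remote mean-diffusivity
# contrast.

#' Transmural helix-angle profiles
#'
#' Casts one ray from the LV center through each epicardial border pixel,
#' samples the HA map bilinearly at sub-voxel steps along it, discards
#' blood-pool and out-of-myocardium samples, normalizes the surviving
#' segment length to [0, 1] (0 endocardium, 1 epicardium), resamples every
#' ray to a fixed position grid and reports the across-ray median plus
#' mean/sd and median/IQR dispersion bands.
#'
#' @param ha_map helix-angle matrix (degrees, NA outside the myocardium).
#' @param geometry the \code{lv_geometry}.
#' @param n_positions points of the normalized position grid.
#' @param step ray sampling step in voxels.
#' @return Class \code{transmural_profile}: \code{position},
#'   \code{median}, \code{mean}, \code{sd}, \code{q1}, \code{q3}, and the
#'   ray count \code{n_rays}.
#' @export
transmural_profiles <- function(ha_map, geometry, n_positions = 20, step = 0.25) {
  stopifnot(inherits(geometry, "lv_geometry"))
  border <- epicardial_border(geometry)
  stop_if_not(nrow(border) > 0, "geometry has no epicardial border pixels")
  ctr <- geometry$center
  pos_grid <- seq(0, 1, length.out = n_positions)
  samples <- matrix(NA_real_, nrow(border), n_positions)
  myo_num <- geometry$myo_mask * 1
  for (i in seq_len(nrow(border))) {
    tip <- c(border[i, 1], border[i, 2])
    len <- sqrt(sum((tip - ctr)^2))
    # overshoot the border-pixel center so the epicardial edge is reached;
    # out-of-myocardium samples are discarded below
    ts <- seq(0, 1 + 2 / len, by = step / len)
    rr <- ctr[1] + ts * (tip[1] - ctr[1])
    cc <- ctr[2] + ts * (tip[2] - ctr[2])
    # >= half coverage of the myocardium indicator puts the segment ends at
    # the sub-voxel tissue boundaries
    inside <- bilinear_sample(myo_num, rr, cc) >= 0.5
    rho <- ts * len
    keep <- inside & rho >= geometry$r_endo - 0.5
    if (sum(keep) < 2) next
    vals <- bilinear_sample_na(ha_map, rr[keep], cc[keep])
    rho_k <- rho[keep]
    u <- (rho_k - min(rho_k)) / (max(rho_k) - min(rho_k))
    fin <- is.finite(vals)
    if (sum(fin) < 2) next
    samples[i, ] <- stats::approx(u[fin], vals[fin], xout = pos_grid, rule = 2)$y
  }
  ok <- rowSums(is.finite(samples)) == n_positions
  stop_if_not(any(ok), "no usable transmural rays")
  s <- samples[ok, , drop = FALSE]
  structure(list(position = pos_grid,
                 median = apply(s, 2, stats::median),
                 mean = colMeans(s),
                 sd = apply(s, 2, stats::sd),
                 q1 = apply(s, 2, stats::quantile, 0.25, names = FALSE),
                 q3 = apply(s, 2, stats::quantile, 0.75, names = FALSE),
                 n_rays = sum(ok)),
            class = "transmural_profile")
}

# myocardial voxels with a 4-neighbor beyond the epicardium (or off-grid);
# returns 0-based (row, col) coordinates
epicardial_border <- function(geometry) {
  m <- geometry$myo_mask
  nr <- nrow(m); nc <- ncol(m)
  outer_ring <- geometry$rho > geometry$r_epi
  pad <- function(mat, dr, dc) {
    out <- matrix(TRUE, nr, nc)   # off-grid counts as outside
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- outer_ring[rs[okr], cs[okc]]
    out
  }
  nb_outside <- pad(outer_ring, 1, 0) | pad(outer_ring, -1, 0) |
    pad(outer_ring, 0, 1) | pad(outer_ring, 0, -1)
  idx <- which(m & nb_outside, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}

# bilinear sampling that ignores NA corners (weight renormalization)
bilinear_sample_na <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  acc_v <- numeric(length(r)); acc_w <- numeric(length(r))
  corner <- function(ri, ci, w) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    v <- rep(NA_real_, length(ri))
    v[ok] <- m[cbind(ri[ok] + 1, ci[ok] + 1)]
    good <- ok & is.finite(v)
    acc_v[good] <<- acc_v[good] + v[good] * w[good]
    acc_w[good] <<- acc_w[good] + w[good]
  }
  corner(r0, c0, (1 - fr) * (1 - fc))
  corner(r0 + 1, c0, fr * (1 - fc))
  corner(r0, c0 + 1, (1 - fr) * fc)
  corner(r0 + 1, c0 + 1, fr * fc)
  ifelse(acc_w > 0, acc_v / acc_w, NA_real_)
}

#' Three-zone fractional-anisotropy analysis
#'
#' Divides the myocardial thickness into three equal-width transmural zones
#' (endocardium [0, 1/3), mesocardium [1/3, 2/3), epicardium [2/3, 1]) and
#' reports the per-zone median FA.
#'
#' @param fa_map FA matrix (NA outside the myocardium).
#' @param geometry the \code{lv_geometry} providing transmural depth.
#' @return Named numeric: \code{endo}, \code{meso}, \code{epi}.
#' @export
fa_zones <- function(fa_map, geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  d <- geometry$depth
  zones <- list(endo = d >= 0 & d < 1 / 3,
                meso = d >= 1 / 3 & d < 2 / 3,
                epi = d >= 2 / 3 & d <= 1)
  vapply(zones, function(z) {
    z[is.na(z)] <- FALSE
    v <- fa_map[z & geometry$myo_mask]
    v <- v[is.finite(v)]
    stop_if_not(length(v) > 0, "empty transmural zone")
    stats::median(v)
  }, 0)
}

#' Infarct-remote mean-diffusivity contrast
#'
#' \code{mean(MD over lesion) - mean(MD over remote)} on disjoint nonempty
#' masks.
#'
#' @param md_map MD matrix (mm^2/s).
#' @param lesion_mask,remote_mask disjoint logical masks.
#' @return Scalar delta-MD in the units of \code{md_map}.
#' @export
delta_md <- function(md_map, lesion_mask, remote_mask) {
  stop_if_not(any(lesion_mask) && any(remote_mask), "lesion and remote masks must be nonempty")
  stop_if_not(!any(lesion_mask & remote_mask), "lesion and remote masks overlap")
  mean(md_map[lesion_mask], na.rm = TRUE) - mean(md_map[remote_mask], na.rm = TRUE)
}

#' Cohort composition percentages
#'
#' Relative percentage of each condition in a cohort table.
#'
#' @param counts data frame with columns \code{condition} and \code{n}.
#' @return The table with a \code{percentage} column (100 n / total).
#' @export
cohort_percentages <- function(counts) {
  stop_if_not(all(c("condition", "n") %in% names(counts)),
              "counts needs 'condition' and 'n' columns")
  counts$percentage <- 100 * counts$n / sum(counts$n)
  counts
}
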