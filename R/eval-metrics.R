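# Error metrics for cDTI map comparison: wraparound-aware angular error,
# per-subject masked map errors, cohort median [IQR] summaries and the
# patch-level model comparison.

#' Absolute angle error with 180-degree wraparound
#'
#' Helix-angle maps identify orientations differing by 180 degrees, so the
#' elementwise error is \code{|x - y|} when below 90 degrees and
#' \code{180 - |x - y|} otherwise; 90 degrees is the maximum possible
#' directional difference. Vectorized over maps; NAs propagate.
#'
#' @param x_deg,y_deg angles in degrees, range [-90, 90].
#' @return Elementwise angular error in [0, 90] degrees.
#' @export
maae <- function(x_deg, y_deg) {
  ok <- is.na(x_deg) | is.na(y_deg) |
    (abs(x_deg) <= 90 & abs(y_deg) <= 90)
  if (!all(ok)) stop("angle inputs must lie in [-90, 90] degrees", call. = FALSE)
  d <- abs(x_deg - y_deg)
  ifelse(d < 90, d, 180 - d)
}

#' Per-subject map errors against a reference
#'
#' Voxel-mean errors over the left-ventricular mask: HA by the wraparound
#' angular error, E2A by the absolute error of absolute angles, MD and FA by
#' plain absolute error. Voxels where either map is undefined (NA) are
#' ignored.
#'
#' @param pred_maps,ref_maps \code{cdti_maps} (or lists with md/fa/ha/e2a
#'   matrices).
#' @param mask logical matrix; evaluation restricted to these voxels.
#' @return One-row data frame: \code{ha_maae}, \code{e2a_mae} (degrees),
#'   \code{md_mae} (mm^2/s), \code{fa_mae}.
#' @export
map_errors <- function(pred_maps, ref_maps, mask) {
  idx <- which(mask)
  stop_if_not(length(idx) > 0, "empty evaluation mask")
  mmean <- function(v) mean(v, na.rm = TRUE)
  data.frame(
    ha_maae = mmean(maae(pred_maps$ha[idx], ref_maps$ha[idx])),
    e2a_mae = mmean(abs(abs(pred_maps$e2a[idx]) - abs(ref_maps$e2a[idx]))),
    md_mae = mmean(abs(pred_maps$md[idx] - ref_maps$md[idx])),
    fa_mae = mmean(abs(pred_maps$fa[idx] - ref_maps$fa[idx])))
}

#' Cohort summary: median [IQR] per metric
#'
#' Summaries are computed across subjects (never pooling voxels) with
#' linear-interpolation quantiles; IQR is Q3 - Q1.
#'
#' @param entries data frame of per-subject errors (one row per subject).
#' @return Data frame with one row per metric: \code{median} and \code{iqr}.
#' @export
cohort_summary <- function(entries) {
  stop_if_not(nrow(entries) >= 1, "need at least one subject")
  num <- entries[vapply(entries, is.numeric, TRUE)]
  out <- data.frame(metric = names(num),
                    median = vapply(num, stats::median, 0),
                    iqr = vapply(num, function(v)
                      diff(stats::quantile(v, c(0.25, 0.75), names = FALSE)), 0))
  rownames(out) <- NULL
  out
}

#' Patch-level error comparison between two models
#'
#' Tiles the grid with non-overlapping \code{patch_size} square patches
#' anchored at the mask bounding-box origin, keeps tiles containing at least
#' one masked voxel, averages each error map over the masked voxels per
#' tile, and reports the fraction of tiles where model A's error is strictly
#' lower than model B's (ties excluded from the numerator).
#'
#' @param err_map_a,err_map_b voxelwise absolute-error maps.
#' @param mask logical evaluation mask.
#' @param patch_size tile side in voxels (default 5).
#' @return List: \code{fraction_a_better}, \code{n_patches}, and the
#'   per-tile mean errors \code{a}, \code{b}.
#' @export
patchwise_comparison <- function(err_map_a, err_map_b, mask, patch_size = 5) {
  stop_if_not(patch_size >= 1, "patch_size must be at least 1")
  stop_if_not(all(dim(err_map_a) == dim(mask)) && all(dim(err_map_b) == dim(mask)),
              "error maps and mask must share dimensions")
  idx <- which(mask, arr.ind = TRUE)
  stop_if_not(nrow(idx) > 0, "no qualifying patch: mask is empty")
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  tile_r <- (idx[, 1] - r0) %/% patch_size
  tile_c <- (idx[, 2] - c0) %/% patch_size
  key <- paste(tile_r, tile_c)
  lin <- (idx[, 2] - 1) * nrow(mask) + idx[, 1]
  a <- tapply(err_map_a[lin], key, mean, na.rm = TRUE)
  b <- tapply(err_map_b[lin], key, mean, na.rm = TRUE)
  keep <- is.finite(a) & is.finite(b)
  stop_if_not(any(keep), "no qualifying patch with finite errors")
  list(fraction_a_better = mean(a[keep] < b[keep]),
       n_patches = sum(keep), a = a[keep], b = b[keep])
}
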