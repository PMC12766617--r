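# Spatial augmentation for training pairs: in-plane rotation with proper
# tensor reorientation (D' = R D R^T), and content-aware cropping that is
# guaranteed to retain the full myocardial mask.

# exact 90-degree counter-clockwise rotation of a matrix (about grid center)
rot90_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# reorient tensor channels under an in-plane rotation by theta (degrees):
# rows are (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
reorient_rows <- function(d6, theta_deg) {
  th <- deg2rad(theta_deg)
  cth <- cos(th); sth <- sin(th)
  cbind(cth^2 * d6[, 1] - 2 * cth * sth * d6[, 4] + sth^2 * d6[, 2],
        sth^2 * d6[, 1] + 2 * cth * sth * d6[, 4] + cth^2 * d6[, 2],
        d6[, 3],
        cth * sth * (d6[, 1] - d6[, 2]) + (cth^2 - sth^2) * d6[, 4],
        cth * d6[, 5] - sth * d6[, 6],
        sth * d6[, 5] + cth * d6[, 6])
}

# bilinear sample of a single channel at fractional 0-based (row, col);
# out-of-grid samples return `fill`
bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gv <- function(ri, ci) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    v <- rep(fill, length(ri))
    v[ok] <- m[cbind(ri[ok] + 1, ci[ok] + 1)]
    v
  }
  gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
    gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
}

#' Rotate a tensor field in-plane
#'
#' Rotates the spatial grid about its center by \code{angle_deg}
#' (counter-clockwise) and reorients every tensor with the matching rotation
#' (\code{D' = R D R^T}). Multiples of 90 degrees use exact index
#' permutation; other angles resample channels bilinearly (mask by nearest
#' neighbor).
#'
#' @param tf a \code{tensor_field}.
#' @param angle_deg rotation angle, degrees.
#' @return A rotated \code{tensor_field}.
#' @export
rotate_tensor_field <- function(tf, angle_deg) {
  stopifnot(inherits(tf, "tensor_field"))
  angle_deg <- angle_deg %% 360
  d <- tf$d
  if (angle_deg %% 90 == 0) {
    k <- (angle_deg %/% 90) %% 4
    mask <- tf$mask
    if (k > 0) {
      for (r in seq_len(k)) {
        d <- {
          ch <- lapply(1:6, function(j) rot90_mat(d[, , j]))
          array(unlist(ch), c(dim(ch[[1]]), 6))
        }
        mask <- rot90_mat(mask)
      }
      nv <- prod(dim(mask))
      d <- array(reorient_rows(matrix(d, nv, 6), 90 * k), dim(d))
    }
    return(tensor_field(d, mask))
  }
  nr <- dim(d)[1]; nc <- dim(d)[2]
  ctr <- (c(nr, nc) - 1) / 2
  grid_r <- matrix(0:(nr - 1), nr, nc) - ctr[1]
  grid_c <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) - ctr[2]
  th <- deg2rad(angle_deg)
  # inverse rotation of the (x, y) = (col, row) offsets
  src_c <- cos(th) * grid_c + sin(th) * grid_r + ctr[2]
  src_r <- -sin(th) * grid_c + cos(th) * grid_r + ctr[1]
  out <- array(0, dim(d))
  for (j in 1:6) out[, , j] <- bilinear_sample(d[, , j], as.vector(src_r),
                                               as.vector(src_c))
  mask_new <- matrix(bilinear_sample(tf$mask * 1, as.vector(src_r),
                                     as.vector(src_c)) >= 0.5, nr, nc)
  out <- array(reorient_rows(matrix(out, nr * nc, 6), angle_deg), dim(d))
  tensor_field(out, mask_new)
}

#' Augment a (noisy, target) training pair
#'
#' Rotates both tensor fields identically (with tensor reorientation) and the
#' mask with them, then crops a window that is guaranteed to contain the
#' entire myocardium and pads it to the configured size. The crop offset is
#' drawn uniformly from the admissible range.
#'
#' @param noisy,target \code{tensor_field}s on the same geometry.
#' @param mask logical myocardium mask.
#' @param angle_deg in-plane rotation, degrees.
#' @param crop_spec list with \code{size} (length-2 output size) or NULL for
#'   no cropping.
#' @param seed seed for the crop-offset draw.
#' @return List \code{noisy}, \code{target}, \code{mask} after augmentation.
#' @export
augment_sample <- function(noisy, target, mask, angle_deg = 0, crop_spec = NULL,
                           seed = NULL) {
  stopifnot(inherits(noisy, "tensor_field"), inherits(target, "tensor_field"))
  stop_if_not(identical(dim(noisy$d), dim(target$d)),
              "noisy and target fields must share geometry")
  if (angle_deg %% 360 != 0) {
    noisy <- rotate_tensor_field(tensor_field(noisy$d, mask), angle_deg)
    target <- rotate_tensor_field(tensor_field(target$d, mask), angle_deg)
    mask <- noisy$mask
  }
  if (!is.null(crop_spec)) {
    sz <- crop_spec$size
    stop_if_not(length(sz) == 2 && all(sz >= 1), "crop size must be length 2")
    idx <- which(mask, arr.ind = TRUE)
    stop_if_not(nrow(idx) > 0, "mask is empty; nothing to crop around")
    rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
    cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
    stop_if_not(rmax - rmin + 1 <= sz[1] && cmax - cmin + 1 <= sz[2],
                "myocardium does not fit in the requested crop window")
    nr <- nrow(mask); nc <- ncol(mask)
    pick <- function(lo_min, lo_max) {
      if (lo_max <= lo_min) lo_min else lo_min + floor(stats::runif(1) * (lo_max - lo_min + 1))
    }
    off <- with_seed(seed, {
      r_lo <- max(1, rmax - sz[1] + 1); r_hi <- min(rmin, max(1, nr - sz[1] + 1))
      c_lo <- max(1, cmax - sz[2] + 1); c_hi <- min(cmin, max(1, nc - sz[2] + 1))
      c(pick(r_lo, r_hi), pick(c_lo, c_hi))
    })
    take <- function(arr) {
      out <- array(0, c(sz, dim(arr)[3]))
      rr <- off[1]:min(nr, off[1] + sz[1] - 1)
      cc <- off[2]:min(nc, off[2] + sz[2] - 1)
      out[seq_along(rr), seq_along(cc), ] <- arr[rr, cc, , drop = FALSE]
      out
    }
    mk <- matrix(FALSE, sz[1], sz[2])
    rr <- off[1]:min(nr, off[1] + sz[1] - 1)
    cc <- off[2]:min(nc, off[2] + sz[2] - 1)
    mk[seq_along(rr), seq_along(cc)] <- mask[rr, cc]
    noisy <- tensor_field(take(noisy$d), mk)
    target <- tensor_field(take(target$d), mk)
    mask <- mk
  }
  list(noisy = noisy, target = target, mask = mask)
}
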