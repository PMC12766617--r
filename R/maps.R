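# Eigen-analysis of tensor fields and derivation of the four cDTI maps.
#
# Conventions (fixed so that phantom construction and map derivation are
# exact inverses, which is the tested contract):
#  * eigenvalues sorted descending; eigenvector signs fixed so the first
#    component exceeding 1e-12 in magnitude is positive (determinism);
#  * HA: flip e1 so its circumferential component is non-negative, then
#    HA = atan2(e1 . l, e1 . c) in degrees, range (-90, 90];
#  * E2A: cross-myocyte axis m = normalize(r - (r.e1) e1), in-wall axis
#    k = e1 x m, E2A = |atan2(e2 . m, e2 . k)| folded into [0, 90].

# symmetric eigendecomposition of N x 6 tensor rows -> values + vectors
eigen_rows <- function(d6) {
  n <- nrow(d6)
  val <- matrix(NA_real_, n, 3)
  e1 <- matrix(NA_real_, n, 3); e2 <- e1; e3 <- e1
  for (i in seq_len(n)) {
    m <- matrix(c(d6[i, 1], d6[i, 4], d6[i, 5],
                  d6[i, 4], d6[i, 2], d6[i, 6],
                  d6[i, 5], d6[i, 6], d6[i, 3]), 3, 3)
    eg <- eigen(m, symmetric = TRUE)   # descending eigenvalues
    val[i, ] <- eg$values
    v <- eg$vectors
    for (j in 1:3) {
      first <- which(abs(v[, j]) > 1e-12)[1]
      if (!is.na(first) && v[first, j] < 0) v[, j] <- -v[, j]
    }
    e1[i, ] <- v[, 1]; e2[i, ] <- v[, 2]; e3[i, ] <- v[, 3]
  }
  list(values = val, e1 = e1, e2 = e2, e3 = e3)
}

#' Per-voxel eigendecomposition of a tensor field
#'
#' Sorted (descending) real symmetric eigendecomposition at every masked
#' voxel. Indefinite tensors (negative eigenvalues) are processed without
#' projection. Eigenvector signs follow a deterministic first-nonzero-positive
#' convention.
#'
#' @param tf a \code{tensor_field}.
#' @return Class \code{eigen_field}: voxel indices \code{idx}, N x 3
#'   \code{values}, and N x 3 eigenvector matrices \code{e1}, \code{e2},
#'   \code{e3}.
#' @export
eigendecompose <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  stop_if_not(all(is.finite(tf$d)), "tensor field contains non-finite elements")
  idx <- which(tf$mask)
  eg <- eigen_rows(tensor_rows(tf, idx))
  structure(c(list(idx = idx, grid_shape = dim(tf$d)[1:2], mask = tf$mask), eg),
            class = "eigen_field")
}

#' Mean diffusivity and fractional anisotropy maps
#'
#' MD is the eigenvalue mean; FA is the standard normalized eigenvalue
#' dispersion \code{sqrt(3/2) * sqrt(sum((lambda - MD)^2)) /
#' sqrt(sum(lambda^2))}. All-zero voxels get FA 0 and are flagged.
#'
#' @param ef an \code{eigen_field}.
#' @return List of \code{md} and \code{fa} matrices (NA outside the mask) and
#'   a logical \code{flag_zero} matrix marking all-zero voxels.
#' @export
compute_md_fa <- function(ef) {
  stopifnot(inherits(ef, "eigen_field"))
  lam <- ef$values
  md_v <- rowMeans(lam)
  ss <- rowSums(lam^2)
  zero <- ss == 0
  fa_v <- ifelse(zero, 0, sqrt(1.5 * rowSums((lam - md_v)^2) / ifelse(zero, 1, ss)))
  md <- matrix(NA_real_, ef$grid_shape[1], ef$grid_shape[2])
  fa <- md; fz <- matrix(FALSE, ef$grid_shape[1], ef$grid_shape[2])
  md[ef$idx] <- md_v; fa[ef$idx] <- fa_v; fz[ef$idx] <- zero
  list(md = md, fa = fa, flag_zero = fz)
}

#' Helix-angle map
#'
#' The primary eigenvector is sign-flipped so its circumferential component
#' is non-negative, then HA is the angle of its projection onto the
#' circumferential-longitudinal plane, \code{atan2(e1 . l, e1 . c)} in
#' degrees, range (-90, 90]. Voxels whose primary eigenvector has no
#' tangential component (exactly radial) are flagged NA.
#'
#' @param ef an \code{eigen_field}.
#' @param frame the matching \code{lv_frame}.
#' @return List: \code{ha} matrix (degrees, NA outside mask or where
#'   undefined) and logical \code{flag_radial}.
#' @export
compute_ha <- function(ef, frame) {
  stopifnot(inherits(ef, "eigen_field"), inherits(frame, "lv_frame"))
  stop_if_not(identical(frame$idx, ef$idx),
              "frame and eigen field are defined on different masks")
  c_comp <- rowSums(ef$e1 * frame$circ)
  l_comp <- rowSums(ef$e1 * frame$long)
  flip <- c_comp < 0 | (c_comp == 0 & l_comp < 0)
  c_comp[flip] <- -c_comp[flip]; l_comp[flip] <- -l_comp[flip]
  undef <- abs(c_comp) < 1e-12 & abs(l_comp) < 1e-12
  ha_v <- rad2deg(atan2(l_comp, c_comp))
  ha_v[undef] <- NA_real_
  ha <- matrix(NA_real_, ef$grid_shape[1], ef$grid_shape[2])
  fr <- matrix(FALSE, ef$grid_shape[1], ef$grid_shape[2])
  ha[ef$idx] <- ha_v; fr[ef$idx] <- undef
  list(ha = ha, flag_radial = fr)
}

#' Absolute second-eigenvector (sheetlet) angle map
#'
#' In the cross-myocyte plane spanned by \code{m = normalize(r - (r.e1) e1)}
#' (cross-myocyte axis) and \code{k = e1 x m} (in-wall axis), E2A is
#' \code{|atan2(e2 . m, e2 . k)|} folded into [0, 90] degrees (absolute-angle
#' convention). Voxels with e1 parallel to the radial axis or with a
#' degenerate lambda2 = lambda3 pair are flagged.
#'
#' @param ef an \code{eigen_field}.
#' @param frame the matching \code{lv_frame}.
#' @return List: \code{e2a} matrix (degrees) and logical \code{flag_degenerate}.
#' @export
compute_e2a <- function(ef, frame) {
  stopifnot(inherits(ef, "eigen_field"), inherits(frame, "lv_frame"))
  stop_if_not(identical(frame$idx, ef$idx),
              "frame and eigen field are defined on different masks")
  r_dot_e1 <- rowSums(frame$radial * ef$e1)
  m_raw <- frame$radial - r_dot_e1 * ef$e1
  m_norm <- sqrt(rowSums(m_raw^2))
  deg_radial <- m_norm < 1e-10
  m_ax <- m_raw / ifelse(deg_radial, 1, m_norm)
  k_ax <- cross3(ef$e1, m_ax)
  ang <- abs(rad2deg(atan2(rowSums(ef$e2 * m_ax), rowSums(ef$e2 * k_ax))))
  ang <- ifelse(ang > 90, 180 - ang, ang)
  scale <- pmax(abs(ef$values[, 1]), .Machine$double.eps)
  deg_pair <- abs(ef$values[, 2] - ef$values[, 3]) / scale < 1e-12
  flag <- deg_radial | deg_pair
  ang[deg_radial] <- NA_real_
  e2a <- matrix(NA_real_, ef$grid_shape[1], ef$grid_shape[2])
  fl <- matrix(FALSE, ef$grid_shape[1], ef$grid_shape[2])
  e2a[ef$idx] <- ang; fl[ef$idx] <- flag
  list(e2a = e2a, flag_degenerate = fl)
}

#' Derive the four cDTI maps from a tensor field
#'
#' Convenience wrapper running the eigendecomposition and all four map
#' computations on a shared local frame.
#'
#' @param tf a \code{tensor_field}.
#' @param frame an \code{lv_frame} on the same mask.
#' @return Class \code{cdti_maps}: \code{md}, \code{fa}, \code{ha},
#'   \code{e2a} matrices (NA outside the mask), the \code{mask}, and
#'   per-map flags.
#' @export
cdti_maps <- function(tf, frame) {
  ef <- eigendecompose(tf)
  mf <- compute_md_fa(ef)
  ha <- compute_ha(ef, frame)
  e2a <- compute_e2a(ef, frame)
  structure(list(md = mf$md, fa = mf$fa, ha = ha$ha, e2a = e2a$e2a,
                 mask = tf$mask,
                 flags = list(zero = mf$flag_zero, radial = ha$flag_radial,
                              degenerate = e2a$flag_degenerate)),
            class = "cdti_maps")
}
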