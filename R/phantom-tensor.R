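#' Diffusion tensor field container
#'
#' A per-voxel symmetric 3 x 3 diffusion tensor stored as its six unique
#' elements in channel order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), units mm^2/s.
#' Positive semi-definiteness is deliberately not enforced anywhere in the
#' pipeline; fitted and de-noised tensors may carry negative eigenvalues.
#'
#' @param d numeric array (rows, cols, 6).
#' @param mask logical matrix of the voxels on which the field is defined.
#' @return Object of class \code{tensor_field}.
#' @export
tensor_field <- function(d, mask) {
  stop_if_not(length(dim(d)) == 3 && dim(d)[3] == 6,
              "d must be a (rows, cols, 6) array")
  stop_if_not(is.logical(mask) && all(dim(mask) == dim(d)[1:2]),
              "mask must be a logical matrix matching the grid")
  stop_if_not(all(is.finite(d)), "tensor elements must be finite")
  structure(list(d = d, mask = mask), class = "tensor_field")
}

# six unique elements at the masked voxels, as an N x 6 matrix
tensor_rows <- function(tf, idx = which(tf$mask)) {
  nvox <- prod(dim(tf$d)[1:2])
  matrix(tf$d[outer(idx, (0:5) * nvox, `+`)], ncol = 6)
}

# write an N x 6 matrix back into the field at the given voxels
`tensor_rows<-` <- function(tf, idx, value) {
  nvox <- prod(dim(tf$d)[1:2])
  tf$d[outer(idx, (0:5) * nvox, `+`)] <- value
  tf
}

#' Eigenvalues from prescribed MD, FA and secondary-anisotropy ratio
#'
#' Solves for lambda1 >= lambda2 >= lambda3 > 0 with mean (lambda1 + lambda2 +
#' lambda3)/3 = MD, the standard fractional-anisotropy closed form equal to
#' the prescribed FA, and lambda2/lambda3 fixed at \code{shape_ratio}. Writing
#' lambda3 = t, the FA constraint pins the second moment of the eigenvalues,
#' which reduces to a quadratic in t solved exactly; the root with
#' lambda1 >= lambda2 is taken. FA = 0 returns the isotropic triple
#' (the shape ratio is vacuous there). For a given shape_ratio > 1 there is a
#' minimum attainable positive FA; prescriptions below it (or above the
#' stick limit) are rejected as infeasible.
#'
#' @param md mean diffusivity, mm^2/s (vectorized).
#' @param fa fractional anisotropy in [0, 1) (vectorized).
#' @param shape_ratio lambda2/lambda3, > 1 so the second eigenvector is
#'   non-degenerate and E2A is well defined.
#' @return N x 3 matrix of eigenvalues (descending).
#' @export
eigenvalues_from_md_fa <- function(md, fa, shape_ratio = 1.5) {
  stop_if_not(all(md > 0), "md_map must be positive")
  stop_if_not(all(fa >= 0 & fa < 1), "fa_map must lie in [0, 1)")
  stop_if_not(shape_ratio > 1, "shape_ratio must exceed 1")
  n <- max(length(md), length(fa))
  md <- rep_len(md, n); fa <- rep_len(fa, n)
  k <- shape_ratio
  a <- 3 * md
  lam <- matrix(md, n, 3)
  aniso <- fa > 0
  if (any(aniso)) {
    s_target <- (a[aniso]^2 / 3) / (1 - (2 / 3) * fa[aniso]^2)
    A <- (1 + k)^2 + k^2 + 1
    B <- 2 * a[aniso] * (1 + k)
    C <- a[aniso]^2 - s_target
    disc <- B^2 - 4 * A * C
    if (any(disc < 0))
      stop("infeasible (MD, FA, shape_ratio) combination: no real eigenvalue solution",
           call. = FALSE)
    t3 <- (B - sqrt(disc)) / (2 * A)
    l1 <- a[aniso] - (1 + k) * t3
    l2 <- k * t3
    bad <- !(l1 >= l2 - 1e-15 & t3 > 0)
    if (any(bad))
      stop(sprintf(
        "infeasible (MD, FA, shape_ratio): positive FA below the minimum %.4f attainable at shape_ratio %g",
        (k - 1) / sqrt(2 * k^2 + 1), k), call. = FALSE)
    lam[aniso, ] <- cbind(l1, l2, t3)
  }
  lam
}

#' Construct a ground-truth tensor field from prescribed maps
#'
#' Inverse of the map-derivation pipeline: per myocardial voxel the
#' eigenvalues are solved from (MD, FA, shape_ratio) and the eigenvectors are
#' assembled from the local cardiac frame so that recomputing HA and E2A from
#' the result returns the prescribed orientation exactly. The primary
#' eigenvector lies in the circumferential-longitudinal plane at the helix
#' angle; the second eigenvector sits in the cross-myocyte plane at the
#' sheetlet angle from the in-wall axis.
#'
#' @param orientation an \code{lv_orientation}.
#' @param md_map mean diffusivity prescription, scalar or matrix (mm^2/s).
#' @param fa_map fractional anisotropy prescription, scalar or matrix.
#' @param shape_ratio lambda2/lambda3 (> 1).
#' @return A \code{tensor_field} on the myocardial mask (zero elsewhere).
#' @export
build_tensor_field <- function(orientation, md_map = 1.0e-3, fa_map = 0.45,
                               shape_ratio = 1.5) {
  stopifnot(inherits(orientation, "lv_orientation"))
  fr <- orientation$frame
  idx <- fr$idx
  md <- if (is.matrix(md_map)) md_map[idx] else rep_len(md_map, length(idx))
  fa <- if (is.matrix(fa_map)) fa_map[idx] else rep_len(fa_map, length(idx))
  lam <- eigenvalues_from_md_fa(md, fa, shape_ratio)

  ha <- deg2rad(orientation$ha[idx])
  e2a <- deg2rad(orientation$e2a[idx])
  e1 <- cos(ha) * fr$circ + sin(ha) * fr$long
  # e1 is orthogonal to the radial axis by construction, so the cross-myocyte
  # axis m reduces to the radial vector and the in-wall axis is e1 x m
  m_ax <- fr$radial
  k_ax <- cross3(e1, m_ax)
  e2 <- sin(e2a) * m_ax + cos(e2a) * k_ax
  e3 <- cross3(e1, e2)

  d6 <- compose_tensor_rows(lam, e1, e2, e3)
  d <- array(0, c(fr$grid_shape, 6))
  nvox <- prod(fr$grid_shape)
  d[outer(idx, (0:5) * nvox, `+`)] <- d6
  mask <- matrix(FALSE, fr$grid_shape[1], fr$grid_shape[2])
  mask[idx] <- TRUE
  tensor_field(d, mask)
}

# D = sum_i lambda_i v_i v_i^T, rowwise; returns N x 6 (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz)
compose_tensor_rows <- function(lam, e1, e2, e3) {
  comp <- function(v, l) cbind(l * v[, 1]^2, l * v[, 2]^2, l * v[, 3]^2,
                               l * v[, 1] * v[, 2], l * v[, 1] * v[, 3],
                               l * v[, 2] * v[, 3])
  comp(e1, lam[, 1]) + comp(e2, lam[, 2]) + comp(e3, lam[, 3])
}

#' Lesion (infarct) specification
#'
#' An angular sector of the myocardial annulus with its own mean diffusivity
#' and fractional anisotropy, emulating the elevated-MD signature of acute
#' infarcts against remote myocardium.
#'
#' @param theta_start_deg sector start angle, degrees in [0, 360).
#' @param theta_width_deg sector width, degrees in (0, 360).
#' @param md_lesion lesion mean diffusivity, mm^2/s (> 0).
#' @param fa_lesion lesion fractional anisotropy in [0, 1).
#' @return Object of class \code{lesion_spec}.
#' @export
lesion_spec <- function(theta_start_deg, theta_width_deg,
                        md_lesion = 1.25e-3, fa_lesion = 0.25) {
  stop_if_not(theta_start_deg >= 0 && theta_start_deg < 360,
              "sector start must lie in [0, 360)")
  stop_if_not(theta_width_deg > 0 && theta_width_deg <= 360,
              "lesion sector width must be positive")
  stop_if_not(md_lesion > 0, "md_lesion must be positive")
  stop_if_not(fa_lesion >= 0 && fa_lesion < 1, "fa_lesion must lie in [0, 1)")
  structure(list(theta_start_deg = theta_start_deg,
                 theta_width_deg = theta_width_deg,
                 md_lesion = md_lesion, fa_lesion = fa_lesion),
            class = "lesion_spec")
}

#' Insert an infarct into a tensor field
#'
#' Voxels of the lesion sector are rebuilt with the lesion MD/FA while keeping
#' each voxel's eigenvectors (myocyte and sheetlet orientation are preserved;
#' only the diffusion magnitude/anisotropy change). Remote voxels are returned
#' bit-identical to the input.
#'
#' @param tf a \code{tensor_field} on a myocardial mask.
#' @param geometry the matching \code{lv_geometry}.
#' @param lesion a \code{lesion_spec}.
#' @param shape_ratio secondary anisotropy used to rebuild lesion eigenvalues.
#' @return List: \code{field} (modified \code{tensor_field}),
#'   \code{lesion_mask}, \code{remote_mask}.
#' @export
add_infarct <- function(tf, geometry, lesion, shape_ratio = 1.5) {
  stopifnot(inherits(tf, "tensor_field"), inherits(geometry, "lv_geometry"),
            inherits(lesion, "lesion_spec"))
  nr <- geometry$grid_shape[1]
  idx_all <- which(geometry$myo_mask)
  row0 <- (idx_all - 1) %% nr
  col0 <- (idx_all - 1) %/% nr
  theta <- (rad2deg(atan2(row0 - geometry$center[1],
                          col0 - geometry$center[2])) + 360) %% 360
  rel <- (theta - lesion$theta_start_deg + 360) %% 360
  in_sector <- rel < lesion$theta_width_deg
  stop_if_not(any(in_sector), "lesion sector does not intersect the myocardium")
  idx_les <- idx_all[in_sector]

  eig <- eigen_rows(tensor_rows(tf, idx_les))
  lam <- eigenvalues_from_md_fa(rep(lesion$md_lesion, length(idx_les)),
                                rep(lesion$fa_lesion, length(idx_les)),
                                shape_ratio)
  d6 <- compose_tensor_rows(lam, eig$e1, eig$e2, eig$e3)
  tensor_rows(tf, idx_les) <- d6

  lesion_mask <- matrix(FALSE, nr, geometry$grid_shape[2])
  lesion_mask[idx_les] <- TRUE
  remote_mask <- geometry$myo_mask & !lesion_mask
  list(field = tf, lesion_mask = lesion_mask, remote_mask = remote_mask)
}

#' Single-subject LV phantom
#'
#' Bundles geometry, orientation prescription, the ground-truth tensor field
#' and a unit proton-density map into one synthetic subject. Defaults follow
#' conventional healthy-myocardium values: helix angle +60 deg (endo) to
#' -60 deg (epi), sheetlet angle 20 deg, MD 1.0e-3 mm^2/s, FA 0.45.
#'
#' @param grid_shape grid size (rows, cols).
#' @param center LV center (row, col), 0-based; default grid center.
#' @param r_endo,r_epi radii in voxels.
#' @param ha_endo_deg,ha_epi_deg,e2a_deg orientation prescription, degrees.
#' @param md,fa diffusivity and anisotropy prescription.
#' @param shape_ratio lambda2/lambda3.
#' @param sit mirrored (situs inversus) chirality.
#' @param s0 proton-density (b = 0 signal) value inside the myocardium.
#' @return Class \code{lv_phantom}: geometry, orientation, tensor field, the
#'   four ground-truth maps and the S0 map.
#' @export
lv_phantom <- function(grid_shape = c(64, 64), center = NULL,
                       r_endo = 11, r_epi = 24,
                       ha_endo_deg = 60, ha_epi_deg = -60, e2a_deg = 20,
                       md = 1.0e-3, fa = 0.45, shape_ratio = 1.5,
                       sit = FALSE, s0 = 1) {
  geom <- make_lv_geometry(grid_shape, center, r_endo, r_epi)
  orient <- prescribe_orientation(geom, ha_endo_deg, ha_epi_deg, e2a_deg, sit)
  tf <- build_tensor_field(orient, md, fa, shape_ratio)
  s0_map <- matrix(0, grid_shape[1], grid_shape[2])
  s0_map[geom$myo_mask] <- s0
  truth <- list(md = ifelse(geom$myo_mask, md, NA_real_),
                fa = ifelse(geom$myo_mask, fa, NA_real_),
                ha = orient$ha, e2a = orient$e2a)
  structure(list(geometry = geom, orientation = orient, tensor = tf,
                 truth = truth, s0 = s0_map,
                 params = list(grid_shape = grid_shape, r_endo = r_endo,
                               r_epi = r_epi, ha_endo_deg = ha_endo_deg,
                               ha_epi_deg = ha_epi_deg, e2a_deg = e2a_deg,
                               md = md, fa = fa, shape_ratio = shape_ratio,
                               sit = sit)),
            class = "lv_phantom")
}

#' Seeded cohort of randomized LV phantoms
#'
#' Draws per-subject geometry and tissue parameters from narrow uniform
#' ranges around the healthy defaults, emulating inter-subject variability in
#' wall radii, LV position and tissue properties.
#'
#' @param n number of subjects.
#' @param grid_shape grid size shared by the cohort.
#' @param seed cohort seed (one stream drives all subjects).
#' @param sit mirrored chirality for every subject.
#' @return List of \code{lv_phantom} objects named \code{subject_01}, ...
#' @export
phantom_cohort <- function(n, grid_shape = c(64, 64), seed = 1, sit = FALSE) {
  stop_if_not(n >= 1, "n must be at least 1")
  half <- min(grid_shape) / 2
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      r_endo <- stats::runif(1, 0.13, 0.17) * min(grid_shape)
      r_epi <- r_endo + stats::runif(1, 0.13, 0.19) * min(grid_shape)
      jit <- min(2, half - r_epi - 1)
      center <- (grid_shape - 1) / 2 + stats::runif(2, -jit, jit)
      ph <- lv_phantom(grid_shape = grid_shape, center = center,
                       r_endo = r_endo, r_epi = r_epi,
                       ha_endo_deg = stats::runif(1, 50, 70),
                       ha_epi_deg = stats::runif(1, -70, -50),
                       e2a_deg = stats::runif(1, 10, 30),
                       md = stats::runif(1, 0.9e-3, 1.1e-3),
                       fa = stats::runif(1, 0.40, 0.50),
                       sit = sit)
      ph
    }) |> stats::setNames(sprintf("subject_%02d", seq_len(n)))
  })
}
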