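#' Analytic short-axis left-ventricle geometry
#'
#' Builds an annular myocardium on a regular voxel grid. Voxel centers sit at
#' integer coordinates (0-based), row-major; the LV center may be fractional.
#' The myocardium is the annulus \code{r_endo <= rho <= r_epi} where
#' \code{rho} is the in-plane distance of a voxel center from the LV center,
#' the blood pool is \code{rho < r_endo}, and transmural depth is
#' \code{(rho - r_endo) / (r_epi - r_endo)} (0 at the endocardium, 1 at the
#' epicardium).
#'
#' @param grid_shape integer length-2, (rows, cols).
#' @param center numeric length-2, LV center as (row, col) in 0-based
#'   continuous coordinates. Defaults to the grid center.
#' @param r_endo,r_epi endocardial and epicardial radii in voxels;
#'   \code{r_epi > r_endo > 0} and the annulus must fit inside the grid.
#' @return An object of class \code{lv_geometry}: grid shape, center, radii,
#'   logical \code{myo_mask} and \code{blood_mask} matrices, a \code{depth}
#'   matrix (NA outside the myocardium) and the distance field \code{rho}.
#' @export
make_lv_geometry <- function(grid_shape, center = NULL, r_endo, r_epi) {
  stop_if_not(length(grid_shape) == 2 && all(grid_shape >= 4),
              "grid_shape must be two integers >= 4")
  if (is.null(center)) center <- (grid_shape - 1) / 2
  stop_if_not(length(center) == 2, "center must be (row, col)")
  stop_if_not(is.numeric(r_endo) && is.numeric(r_epi) &&
                r_endo > 0 && r_epi > r_endo,
              sprintf("radii out of order: need r_epi > r_endo > 0, got r_endo=%g, r_epi=%g",
                      r_endo, r_epi))
  # annulus must fit strictly inside the grid (0-based coordinates)
  fits <- center[1] - r_epi >= 0 && center[1] + r_epi <= grid_shape[1] - 1 &&
    center[2] - r_epi >= 0 && center[2] + r_epi <= grid_shape[2] - 1
  stop_if_not(fits, sprintf(
    "annulus exceeds grid: center (%g, %g), r_epi %g does not fit in %d x %d",
    center[1], center[2], r_epi, grid_shape[1], grid_shape[2]))

  nr <- grid_shape[1]; nc <- grid_shape[2]
  row0 <- matrix(0:(nr - 1), nr, nc)          # 0-based row coordinate
  col0 <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  rho <- sqrt((row0 - center[1])^2 + (col0 - center[2])^2)
  myo <- rho >= r_endo & rho <= r_epi
  blood <- rho < r_endo
  depth <- matrix(NA_real_, nr, nc)
  depth[myo] <- (rho[myo] - r_endo) / (r_epi - r_endo)

  structure(list(grid_shape = as.integer(grid_shape), center = as.numeric(center),
                 r_endo = r_endo, r_epi = r_epi,
                 myo_mask = myo, blood_mask = blood,
                 depth = depth, rho = rho),
            class = "lv_geometry")
}

#' Local cardiac coordinate frame
#'
#' Per-myocardial-voxel orthonormal triad: radial \code{r} (in-plane unit
#' vector from the LV center to the voxel), circumferential \code{c = z x r}
#' and longitudinal \code{l = z} (slice normal, out of plane). The 3-vector
#' axes are (x, y, z) = (column, row, slice) directions.
#'
#' @param geometry an \code{lv_geometry}.
#' @return Class \code{lv_frame}: voxel index vector \code{idx} (into the
#'   grid, column-major), and N x 3 matrices \code{radial}, \code{circ},
#'   \code{long}.
#' @export
local_frame <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  idx <- which(geometry$myo_mask)
  stop_if_not(length(idx) > 0, "geometry has no myocardial voxels")
  nr <- geometry$grid_shape[1]
  row0 <- (idx - 1) %% nr
  col0 <- (idx - 1) %/% nr
  dx <- col0 - geometry$center[2]   # x = column direction
  dy <- row0 - geometry$center[1]   # y = row direction
  radial <- rows_unit(cbind(dx, dy, 0))
  circ <- cbind(-radial[, 2], radial[, 1], 0)   # z x r
  long <- matrix(rep(c(0, 0, 1), each = length(idx)), ncol = 3)
  structure(list(idx = idx, radial = radial, circ = circ, long = long,
                 grid_shape = geometry$grid_shape),
            class = "lv_frame")
}

#' Prescribe myocyte and sheetlet orientation
#'
#' Helix angle varies linearly with transmural depth between the endocardial
#' and epicardial values; the sheetlet (E2) angle is constant. With
#' \code{sit = TRUE} the helix-angle map is negated everywhere, emulating the
#' mirrored myocyte chirality of situs inversus totalis.
#'
#' @param geometry an \code{lv_geometry}.
#' @param ha_endo_deg,ha_epi_deg helix angle at depth 0 and 1, degrees in
#'   [-90, 90].
#' @param e2a_deg sheetlet angle, degrees in [0, 90].
#' @param sit logical; mirrored (situs inversus) chirality.
#' @return Class \code{lv_orientation}: the local frame, \code{ha} and
#'   \code{e2a} matrices (degrees, NA outside the myocardium) and the flag
#'   \code{sit}.
#' @export
prescribe_orientation <- function(geometry, ha_endo_deg = 60, ha_epi_deg = -60,
                                  e2a_deg = 20, sit = FALSE) {
  stopifnot(inherits(geometry, "lv_geometry"))
  stop_if_not(abs(ha_endo_deg) <= 90 && abs(ha_epi_deg) <= 90,
              "helix angles must lie in [-90, 90] degrees")
  stop_if_not(e2a_deg >= 0 && e2a_deg <= 90, "e2a_deg must lie in [0, 90]")
  frame <- local_frame(geometry)   # errors if no myocardial voxels
  ha <- matrix(NA_real_, geometry$grid_shape[1], geometry$grid_shape[2])
  d <- geometry$depth[frame$idx]
  ha_v <- ha_endo_deg + d * (ha_epi_deg - ha_endo_deg)
  if (sit) ha_v <- -ha_v
  ha[frame$idx] <- ha_v
  e2a <- matrix(NA_real_, geometry$grid_shape[1], geometry$grid_shape[2])
  e2a[frame$idx] <- e2a_deg
  structure(list(frame = frame, ha = ha, e2a = e2a, sit = isTRUE(sit)),
            class = "lv_orientation")
}
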