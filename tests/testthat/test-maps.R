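# Eigen-analysis and the four cDTI maps (MD, FA, HA, E2A).

test_that("eigendecomposition handles diagonal, symmetric and indefinite input", {
  rows <- rbind(c(3e-3, 2e-3, 1e-3, 0, 0, 0),
                c(1e-3, 1e-3, -0.5e-3, 0, 0, 0))   # indefinite, no projection
  tf <- field_from_rows(rows)
  ef <- eigendecompose(tf)
  expect_equal(ef$values[1, ], c(3e-3, 2e-3, 1e-3))
  expect_equal(abs(ef$e1[1, ]), c(1, 0, 0))
  expect_equal(ef$values[2, 3], -0.5e-3)           # negative eigenvalue kept
  # reconstruction and orthonormality
  for (i in 1:2) {
    V <- rbind(ef$e1[i, ], ef$e2[i, ], ef$e3[i, ])
    expect_lt(max(abs(V %*% t(V) - diag(3))), 1e-8)
    D <- t(V) %*% diag(ef$values[i, ]) %*% V
    expect_lt(max(abs(D - matrix(c(rows[i, 1], rows[i, 4], rows[i, 5],
                                   rows[i, 4], rows[i, 2], rows[i, 6],
                                   rows[i, 5], rows[i, 6], rows[i, 3]), 3))),
              1e-8 * max(abs(rows)))
  }
  bad <- tf; bad$d[1] <- NaN
  expect_error(eigendecompose(bad), "non-finite")
})

test_that("MD and FA follow their closed forms", {
  rows <- rbind(c(1e-3, 1e-3, 1e-3, 0, 0, 0),
                c(1, 0, 0, 0, 0, 0),
                c(1.8e-3, 0.9e-3, 0.3e-3, 0, 0, 0))
  mf <- compute_md_fa(eigendecompose(field_from_rows(rows)))
  idx <- which(field_from_rows(rows)$mask)
  expect_equal(mf$md[idx[1]], 1e-3); expect_equal(mf$fa[idx[1]], 0)
  expect_equal(mf$fa[idx[2]], 1, tolerance = 1e-12)
  # direct evaluation of the FA formula as the oracle
  lam <- c(1.8, 0.9, 0.3) * 1e-3
  fa_oracle <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(mf$md[idx[3]], 1e-3, tolerance = 1e-12)
  expect_equal(mf$fa[idx[3]], fa_oracle, tolerance = 1e-12)
  # all-zero voxel: FA defined as 0 and flagged
  zrow <- field_from_rows(matrix(0, 1, 6))
  mfz <- compute_md_fa(eigendecompose(zrow))
  expect_equal(mfz$fa[which(zrow$mask)], 0)
  expect_true(mfz$flag_zero[which(zrow$mask)])
})

test_that("helix angle follows the circumferential-longitudinal convention", {
  geom <- small_phantom()$geometry
  fr <- local_frame(geom)
  n <- length(fr$idx)
  lam <- cbind(rep(2e-3, n), 1.2e-3, 0.8e-3)
  rows_unit_test <- function(m) m / sqrt(rowSums(m^2))
  cross_rows <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                     a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                     a[, 1] * b[, 2] - a[, 2] * b[, 1])
  build_ha_field <- function(e1) {
    # complete an orthonormal triad around e1 (e1 lies in the c-l plane here,
    # so the radial axis is never parallel to it)
    e2 <- rows_unit_test(cross_rows(e1, fr$radial))
    e3 <- cross_rows(e1, e2)
    comp <- function(v, l) cbind(l * v[, 1]^2, l * v[, 2]^2, l * v[, 3]^2,
                                 l * v[, 1] * v[, 2], l * v[, 1] * v[, 3],
                                 l * v[, 2] * v[, 3])
    d6 <- comp(e1, lam[, 1]) + comp(e2, lam[, 2]) + comp(e3, lam[, 3])
    d <- array(0, c(geom$grid_shape, 6))
    nvox <- prod(geom$grid_shape)
    d[outer(fr$idx, (0:5) * nvox, `+`)] <- d6
    tensor_field(d, geom$myo_mask)
  }

  # e1 exactly circumferential -> HA = 0
  ha0 <- compute_ha(eigendecompose(build_ha_field(fr$circ)), fr)
  expect_lt(max(abs(ha0$ha[fr$idx])), 1e-8)
  # e1 = (c + l)/sqrt(2) -> 45 degrees
  ha45 <- compute_ha(eigendecompose(build_ha_field((fr$circ + fr$long) / sqrt(2))), fr)
  expect_lt(max(abs(ha45$ha[fr$idx] - 45)), 1e-8)
  # antipodal invariance: negating e1 leaves HA unchanged
  e1r <- rows_unit_test(0.8 * fr$circ + 0.6 * fr$long)
  a <- compute_ha(eigendecompose(build_ha_field(e1r)), fr)
  b <- compute_ha(eigendecompose(build_ha_field(-e1r)), fr)
  expect_equal(a$ha[fr$idx], b$ha[fr$idx], tolerance = 1e-10)
})

test_that("E2A measures the sheetlet angle with absolute folding", {
  geom <- small_phantom()$geometry
  orient0 <- prescribe_orientation(geom, 40, -40, 0)    # e2 on the in-wall axis
  mp0 <- cdti_maps(build_tensor_field(orient0, fa_map = 0.45), orient0$frame)
  expect_lt(max(abs(mp0$e2a[orient0$frame$idx])), 1e-8)
  orient90 <- prescribe_orientation(geom, 40, -40, 90)  # e2 radial
  mp90 <- cdti_maps(build_tensor_field(orient90, fa_map = 0.45), orient90$frame)
  expect_lt(max(abs(mp90$e2a[orient90$frame$idx] - 90)), 1e-8)
  # folding: prescriptions theta and (180 - theta) give mirrored e2 around the
  # wall plane; the absolute convention reports both in [0, 90]
  o35 <- prescribe_orientation(geom, 40, -40, 35)
  mp35 <- cdti_maps(build_tensor_field(o35, fa_map = 0.45), o35$frame)
  expect_lt(max(abs(mp35$e2a[o35$frame$idx] - 35)), 1e-8)
  expect_true(all(mp35$e2a[o35$frame$idx] >= 0 & mp35$e2a[o35$frame$idx] <= 90))
})

test_that("maps are equivariant under exact 90-degree rotation", {
  # centered annulus: the geometry (and its frame) maps onto itself under a
  # quarter turn, so maps of the rotated field equal the rotated maps
  ph <- lv_phantom(grid_shape = c(32, 32), r_endo = 6, r_epi = 12)
  fr <- ph$orientation$frame
  mp <- cdti_maps(ph$tensor, fr)
  tf_rot <- rotate_tensor_field(ph$tensor, 90)
  expect_equal(tf_rot$mask, ph$tensor$mask)   # symmetric mask is invariant
  mp_rot <- cdti_maps(tf_rot, fr)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  expect_equal(mp_rot$md, rot90(mp$md), tolerance = 1e-10)
  expect_equal(mp_rot$fa, rot90(mp$fa), tolerance = 1e-10)
  expect_equal(mp_rot$ha, rot90(mp$ha), tolerance = 1e-8)
  expect_equal(mp_rot$e2a, rot90(mp$e2a), tolerance = 1e-8)
})

test_that("noiseless phantom FA is constant across the wall", {
  ph <- small_phantom(fa = 0.5)
  mp <- cdti_maps(ph$tensor, ph$orientation$frame)
  v <- mp$fa[ph$geometry$myo_mask]
  expect_lt(diff(range(v)), 1e-9)
})
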