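# LV phantom: geometry, orientation prescription, tensor construction,
# infarct insertion.

test_that("annulus masks match the analytic area and radial ordering", {
  geom <- make_lv_geometry(c(128, 128), c(63.5, 63.5), r_endo = 15, r_epi = 40)
  expect_lt(abs(sum(geom$myo_mask) - pi * (40^2 - 15^2)) / (pi * (40^2 - 15^2)),
            0.05)
  ctr <- c(64, 64)  # voxel nearest the center
  expect_true(geom$blood_mask[ctr[1], ctr[2]])
  expect_false(geom$myo_mask[ctr[1], ctr[2]])
  expect_false(any(geom$myo_mask & geom$blood_mask))
  # depth spans [0, 1] and is monotone in the distance from the center
  d <- geom$depth[geom$myo_mask]
  rho <- geom$rho[geom$myo_mask]
  expect_true(all(d >= 0 & d <= 1))
  ord <- order(rho)
  expect_true(all(diff(d[ord]) >= -1e-12))
})

test_that("invalid geometries are rejected", {
  expect_error(make_lv_geometry(c(128, 128), r_endo = 40, r_epi = 15),
               "radii out of order")
  expect_error(make_lv_geometry(c(64, 64), r_endo = 10, r_epi = 40),
               "exceeds grid")
})

test_that("local frame is orthonormal to 1e-10", {
  fr <- local_frame(small_phantom()$geometry)
  vecs <- list(fr$radial, fr$circ, fr$long)
  for (i in 1:3) for (j in 1:3) {
    dots <- rowSums(vecs[[i]] * vecs[[j]])
    expect_lt(max(abs(dots - as.numeric(i == j))), 1e-10)
  }
})

test_that("helix angle is linear in depth and negated for mirrored chirality", {
  geom <- small_phantom()$geometry
  orient <- prescribe_orientation(geom, 60, -60, 20)
  idx <- orient$frame$idx
  expected <- 60 + geom$depth[idx] * (-120)
  expect_equal(orient$ha[idx], expected, tolerance = 1e-12)
  # endo voxels sit at +60, midwall at 0
  endo <- which.min(geom$depth[idx])
  expect_lt(abs(orient$ha[idx][endo] - 60), 1)
  mirror <- prescribe_orientation(geom, 60, -60, 20, sit = TRUE)
  expect_equal(mirror$ha[idx], -orient$ha[idx])
  expect_equal(mirror$e2a[idx], orient$e2a[idx])
  expect_error(prescribe_orientation(geom, 120, -60, 20), "\\[-90, 90\\]")
})

test_that("eigenvalue solve honors MD/FA exactly and flags infeasibility", {
  lam <- eigenvalues_from_md_fa(1e-3, 0)
  expect_equal(lam[1, ], rep(1e-3, 3))
  set.seed(11)
  md <- runif(40, 0.5e-3, 2e-3)
  fa <- runif(40, 0.25, 0.9)
  lam <- eigenvalues_from_md_fa(md, fa, shape_ratio = 1.5)
  expect_equal(rowMeans(lam), md, tolerance = 1e-9)
  fa_back <- sqrt(1.5 * rowSums((lam - rowMeans(lam))^2) / rowSums(lam^2))
  expect_equal(fa_back, fa, tolerance = 1e-9)
  expect_true(all(lam[, 1] >= lam[, 2] & lam[, 2] >= lam[, 3] & lam[, 3] > 0))
  # positive FA below the shape-ratio floor ((k-1)/sqrt(2k^2+1) ~ 0.213) fails
  expect_error(eigenvalues_from_md_fa(1e-3, 0.1, 1.5), "infeasible")
})

test_that("maps recomputed from a built field reproduce the prescription", {
  for (seed in 1:3) {
    set.seed(seed)
    ph <- small_phantom(ha_endo_deg = runif(1, 40, 80),
                        ha_epi_deg = runif(1, -80, -40),
                        e2a_deg = runif(1, 5, 60),
                        md = runif(1, 0.7e-3, 1.5e-3),
                        fa = runif(1, 0.3, 0.6))
    mp <- cdti_maps(ph$tensor, ph$orientation$frame)
    idx <- ph$orientation$frame$idx
    expect_lt(max(abs(mp$ha[idx] - ph$truth$ha[idx])), 1e-6)
    expect_lt(max(abs(mp$e2a[idx] - ph$truth$e2a[idx])), 1e-6)
    expect_lt(max(abs(mp$md[idx] - ph$truth$md[idx])), 1e-6 * 1e-3)
    expect_lt(max(abs(mp$fa[idx] - ph$truth$fa[idx])), 1e-6)
  }
})

test_that("trace of every built tensor matches the prescribed MD", {
  ph <- small_phantom(md = 1.1e-3)
  tr <- ph$tensor$d[, , 1] + ph$tensor$d[, , 2] + ph$tensor$d[, , 3]
  idx <- which(ph$geometry$myo_mask)
  expect_lt(max(abs(tr[idx] / 3 - 1.1e-3) / 1.1e-3), 1e-9)
})

test_that("situs inversus mirrors HA but leaves MD/FA untouched", {
  ph <- small_phantom()
  ph_sit <- small_phantom(sit = TRUE)
  fr <- ph$orientation$frame
  mp <- cdti_maps(ph$tensor, fr)
  mp_sit <- cdti_maps(ph_sit$tensor, fr)
  idx <- fr$idx
  expect_equal(mp_sit$ha[idx], -mp$ha[idx], tolerance = 1e-9)
  expect_equal(mp_sit$md[idx], mp$md[idx], tolerance = 1e-12)
  expect_equal(mp_sit$fa[idx], mp$fa[idx], tolerance = 1e-12)
})

test_that("infarct insertion changes only the lesion sector", {
  ph <- small_phantom(md = 1.05e-3)
  les <- lesion_spec(30, 90, md_lesion = 1.25e-3, fa_lesion = 0.25)
  out <- add_infarct(ph$tensor, ph$geometry, les)
  # remote voxels bit-identical
  remote_idx <- which(out$remote_mask)
  nvox <- prod(dim(ph$tensor$d)[1:2])
  pos <- outer(remote_idx, (0:5) * nvox, `+`)
  expect_identical(out$field$d[pos], ph$tensor$d[pos])
  # prescribed contrast of regional mean MD
  md_map <- compute_md_fa(eigendecompose(out$field))$md
  expect_equal(mean(md_map[out$lesion_mask]) - mean(md_map[out$remote_mask]),
               0.20e-3, tolerance = 1e-12)
  # masks partition the myocardium
  expect_true(all(xor(out$lesion_mask[ph$geometry$myo_mask],
                      out$remote_mask[ph$geometry$myo_mask])))
  expect_error(lesion_spec(30, 0), "width must be positive")
})

test_that("cohort generation is seeded and respects the grid", {
  c1 <- phantom_cohort(4, c(64, 64), seed = 9)
  c2 <- phantom_cohort(4, c(64, 64), seed = 9)
  expect_equal(c1[[3]]$tensor$d, c2[[3]]$tensor$d)
  expect_equal(length(c1), 4)
  for (ph in c1) expect_gt(sum(ph$geometry$myo_mask), 0)
})
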