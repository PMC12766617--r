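# Error metrics, cohort summaries and the clinical-validation analyses.

test_that("wraparound angular error matches its definition exhaustively", {
  expect_equal(maae(10, 30), 20)
  expect_equal(maae(80, -80), 20)    # wraparound branch: 180 - 160
  expect_equal(maae(0, 90), 90)      # maximum directional difference
  g <- seq(-90, 90, by = 1)
  M <- outer(g, g, maae)
  expect_true(all(M >= 0 & M <= 90))
  expect_equal(M, t(M))              # symmetry
  expect_equal(diag(M), rep(0, length(g)))
  expect_error(maae(120, 0), "\\[-90, 90\\]")
  expect_true(is.na(maae(NA, 10)))
})

test_that("map errors aggregate over the mask with the right conventions", {
  mk <- function(v) matrix(v, 2, 2)
  pred <- list(ha = mk(30), e2a = mk(-30), md = mk(1.1e-3), fa = mk(0.5))
  ref <- list(ha = mk(50), e2a = mk(30), md = mk(1.0e-3), fa = mk(0.4))
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  err <- map_errors(pred, ref, mask)
  expect_equal(err$ha_maae, 20)          # single voxel reduces to maae
  expect_equal(err$e2a_mae, 0)           # absolute-angle folding: |-30| = 30
  expect_equal(err$md_mae, 0.1e-3)
  expect_equal(err$fa_mae, 0.1)
  self <- map_errors(ref, ref, mask)
  expect_true(all(unlist(self) == 0))
  expect_error(map_errors(pred, ref, mask & FALSE), "empty")
})

test_that("cohort summaries use linear-interpolation quantiles across subjects", {
  entries <- data.frame(ha_maae = c(1, 2, 3, 4, 5))
  s <- cohort_summary(entries)
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  one <- cohort_summary(data.frame(ha_maae = 7))
  expect_equal(one$iqr, 0)
  perm <- cohort_summary(entries[sample(5), , drop = FALSE])
  expect_equal(perm, s)
})

test_that("transmural profiles recover a prescribed linear HA law", {
  ph <- lv_phantom(grid_shape = c(64, 64), r_endo = 11, r_epi = 24)
  mp <- cdti_maps(ph$tensor, ph$orientation$frame)
  pr <- transmural_profiles(mp$ha, ph$geometry, n_positions = 15)
  expected <- 60 + pr$position * (-120)
  # boundary samples carry a half-voxel partial-volume bias, so the
  # prescribed-line oracle applies to interior wall positions
  interior <- pr$position >= 0.1 & pr$position <= 0.9
  expect_lt(max(abs(pr$median - expected)[interior]), 2)
  expect_lt(max(abs(pr$median - expected)), 6)
  expect_true(all(pr$position >= 0 & pr$position <= 1))
  expect_true(!is.unsorted(pr$position, strictly = TRUE))
  # constant map -> constant profile; symmetric phantom -> rotation-invariant
  const <- ifelse(ph$geometry$myo_mask, 42, NA_real_)
  prc <- transmural_profiles(const, ph$geometry, n_positions = 10)
  expect_lt(max(abs(prc$median - 42)), 1e-9)
  rot <- t(mp$ha)[, 64:1]   # quarter turn of a rotation-symmetric field
  pr_rot <- transmural_profiles(rot, ph$geometry, n_positions = 15)
  expect_lt(max(abs(pr_rot$median - pr$median)), 0.5)
})

test_that("three-zone FA analysis partitions the wall by depth thirds", {
  ph <- lv_phantom(grid_shape = c(64, 64), r_endo = 11, r_epi = 24)
  const <- ifelse(ph$geometry$myo_mask, 0.4, NA_real_)
  z <- fa_zones(const, ph$geometry)
  expect_equal(unname(z), c(0.4, 0.4, 0.4))
  # meso-elevated prescription makes the middle zone strictly largest
  d <- ph$geometry$depth
  meso_up <- ifelse(ph$geometry$myo_mask, 0.4 + 0.2 * exp(-((d - 0.5) / 0.15)^2),
                    NA_real_)
  z2 <- fa_zones(meso_up, ph$geometry)
  expect_gt(z2[["meso"]], z2[["endo"]])
  expect_gt(z2[["meso"]], z2[["epi"]])
  # zones partition the myocardium
  dd <- ph$geometry$depth[ph$geometry$myo_mask]
  n_in_zones <- sum(dd < 1 / 3) + sum(dd >= 1 / 3 & dd < 2 / 3) + sum(dd >= 2 / 3)
  expect_equal(n_in_zones, sum(ph$geometry$myo_mask))
})

test_that("infarct-remote MD contrast behaves arithmetically", {
  md <- matrix(1.05e-3, 8, 8)
  lesion <- matrix(FALSE, 8, 8); lesion[1:4, 1:4] <- TRUE
  remote <- matrix(FALSE, 8, 8); remote[5:8, 5:8] <- TRUE
  md[lesion] <- 1.25e-3
  expect_equal(delta_md(md, lesion, remote), 0.20e-3)
  expect_equal(delta_md(md, remote, lesion), -0.20e-3)   # antisymmetry
  expect_equal(delta_md(matrix(1e-3, 8, 8), lesion, remote), 0)
  expect_error(delta_md(md, lesion, lesion), "overlap")
  # noiseless infarct phantom reproduces the prescribed contrast exactly
  study <- infarct_contrast_study()
  expect_equal(study$delta_md, 0.20e-3, tolerance = 1e-12)
})

test_that("patch-level comparison counts strictly better tiles", {
  mask <- matrix(TRUE, 10, 10)
  a <- matrix(1, 10, 10); b <- matrix(1, 10, 10)
  expect_equal(patchwise_comparison(a, b, mask, 5)$fraction_a_better, 0)
  expect_equal(patchwise_comparison(a / 2, b, mask, 5)$fraction_a_better, 1)
  # two tiles, one better one worse
  mask2 <- matrix(FALSE, 10, 5); mask2[1:10, ] <- TRUE
  a2 <- matrix(1, 10, 5); b2 <- matrix(1, 10, 5)
  a2[1:5, ] <- 0.5       # first tile better
  a2[6:10, ] <- 2        # second tile worse
  res <- patchwise_comparison(a2, b2, mask2, 5)
  expect_equal(res$n_patches, 2)
  expect_equal(res$fraction_a_better, 0.5)
  expect_error(patchwise_comparison(a, b, mask & FALSE, 5), "empty")
})

test_that("cohort percentage table reproduces printed proportions", {
  counts <- utils::read.csv(system.file("extdata", "example_cohort.csv",
                                        package = "cdtidenoise"))
  pct <- cohort_percentages(counts)
  expect_equal(sum(pct$n), 744)
  expect_equal(round(pct$percentage[pct$condition == "Healthy"], 1), 26.5)
  expect_equal(sum(pct$percentage), 100)
})
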