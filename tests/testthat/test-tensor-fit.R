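# Log-linear design matrix, least-squares tensor fitting and the two
# normalization schemes.

test_that("design matrix rows follow the log-linear tensor model", {
  tab <- data.frame(b = c(0, 600, 600),
                    dir_index = c(0L, 1L, 2L),
                    gx = c(0, 1, 0), gy = c(0, 0, 1), gz = c(0, 0, 0))
  tab <- rbind(tab, data.frame(b = 600, dir_index = 3:6,
                               gx = c(0, 1, 1, 0) / sqrt(c(1, 2, 2, 2)),
                               gy = c(0, 1, 0, 1) / sqrt(c(1, 2, 2, 2)),
                               gz = c(1, 0, 1, 1) / sqrt(c(1, 2, 2, 2))))
  dm <- build_design_matrix(tab)
  expect_equal(dm$X[1, ], c(1, 0, 0, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(dm$X[2, ], c(1, -600, 0, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(qr(dm$X)$rank, 7)
  # standard 1 b0 + 6-direction protocol has numerical rank 7
  dm2 <- build_design_matrix(make_protocol("1BH"))
  expect_equal(qr(dm2$X)$rank, 7)
  # a protocol whose directions do not span tensor space is rejected
  bad <- data.frame(b = c(0, rep(600, 6)), dir_index = 0:6,
                    gx = c(0, rep(1, 6)), gy = 0, gz = 0)
  expect_error(build_design_matrix(bad), "rank-deficient")
})

test_that("noiseless fits recover random ground-truth tensors exactly", {
  set.seed(21)
  rows <- random_tensor_rows(50)
  tf <- field_from_rows(rows)
  s0 <- matrix(0, nrow(tf$mask), ncol(tf$mask)); s0[tf$mask] <- 1
  ser <- simulate_dwi(tf, s0, make_protocol("full"), 0)
  avg <- average_repetitions(ser)
  fit <- fit_lls(avg, build_design_matrix(avg), tf$mask)
  scale <- max(abs(rows))
  expect_lt(max(abs(fit$tensor$d - tf$d)) / scale, 1e-9)
  expect_equal(fit$report$n_excluded, 0)
  expect_lt(max(abs(fit$s0[tf$mask] - 1)), 1e-9)
})

test_that("masking and non-positive signals follow the fit contract", {
  ph <- small_phantom()
  ser <- simulate_dwi(ph$tensor, ph$s0, make_protocol("1BH"), 0)
  avg <- average_repetitions(ser)
  des <- build_design_matrix(avg)
  fit <- fit_lls(avg, des, ph$geometry$myo_mask)
  outside <- which(!ph$geometry$myo_mask)[1]
  expect_equal(fit$tensor$d[outside], 0)   # zero-filled outside the mask
  # zero one voxel's signal: excluded and counted, rest unaffected
  bad_vox <- which(ph$geometry$myo_mask)[5]
  avg2 <- avg
  avg2$images[, , 3][bad_vox] <- 0
  fit2 <- fit_lls(avg2, des, ph$geometry$myo_mask)
  expect_equal(fit2$report$n_excluded, 1)
  expect_equal(fit2$report$excluded_idx, bad_vox)
  expect_equal(fit2$tensor$d[bad_vox], 0)
  other <- which(ph$geometry$myo_mask)[10]   # untouched voxel fits identically
  nvox <- prod(dim(avg$images)[1:2])
  expect_equal(fit2$tensor$d[other + (0:5) * nvox],
               fit$tensor$d[other + (0:5) * nvox])
  # all-voxel failure is an error
  avg3 <- avg; avg3$images[, , 1] <- 0
  expect_error(fit_lls(avg3, des, ph$geometry$myo_mask), "non-positive")
})

test_that("duplicating every design row leaves the LLS solution unchanged", {
  ph <- small_phantom()
  ser <- simulate_dwi(ph$tensor, ph$s0, make_protocol("1BH"), 0.03, seed = 3)
  avg <- average_repetitions(ser)
  fit1 <- fit_lls(avg, build_design_matrix(avg), ph$geometry$myo_mask)
  dup <- avg
  dup$images <- array(c(avg$images, avg$images),
                      c(dim(avg$images)[1:2], 2 * dim(avg$images)[3]))
  des1 <- build_design_matrix(avg)
  des_dup <- des1
  des_dup$X <- rbind(des1$X, des1$X)
  fit2 <- fit_lls(dup, des_dup, ph$geometry$myo_mask)
  expect_equal(fit2$tensor$d, fit1$tensor$d, tolerance = 1e-12)
})

test_that("scale normalization matches the 1500 s/mm^2 convention", {
  d <- array(0, c(2, 2, 6)); d[1, 1, ] <- 1.0e-3
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  tf <- tensor_field(d, mask)
  spec <- norm_spec("scale")
  x <- normalize_tensor(tf, spec)
  expect_equal(x[1, 1, 1], 1.5)
  back <- denormalize_tensor(x, spec, mask)
  expect_equal(back$d, tf$d, tolerance = 1e-15)
})

test_that("normalization round-trips and z-scoring standardizes training data", {
  set.seed(31)
  fields <- lapply(1:3, function(i) field_from_rows(random_tensor_rows(30)))
  zspec <- fit_tensor_normalization(fields)
  rows <- do.call(rbind, lapply(fields, function(tf)
    matrix(normalize_tensor(tf, zspec)[array(rep(tf$mask, 6),
                                             c(dim(tf$mask), 6))], ncol = 6)))
  expect_lt(max(abs(colMeans(rows))), 1e-9)
  expect_lt(max(abs(apply(rows, 2, sd) - 1)), 1e-9)
  # round-trip to 1e-12 for random fields under both modes
  for (spec in list(norm_spec("scale"), zspec)) {
    tf <- fields[[1]]
    back <- denormalize_tensor(normalize_tensor(tf, spec), spec, tf$mask)
    expect_lt(max(abs(back$d - tf$d)), 1e-12)
  }
  expect_error(norm_spec("zscore"), "requires fitted channel statistics")
})
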