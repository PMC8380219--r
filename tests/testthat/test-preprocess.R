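test_that("resampling is exact on constants, identities and linear ramps", {
  const <- image_volume(array(2.5, c(10, 12, 9)), c(2, 3, 4))
  out <- resample_volume(const, 5.5)
  expect_true(all(abs(out$values - 2.5) < 1e-12))
  expect_equal(out$spacing_mm, rep(5.5, 3))

  already <- image_volume(array(rnorm(5 * 5 * 5), c(5, 5, 5)), rep(5.5, 3))
  expect_identical(resample_volume(already, 5.5)$values, already$values)

  # Linear ramp along x: trilinear interpolation reproduces it exactly at
  # the new voxel centres.
  n <- c(21, 6, 6)
  ramp <- image_volume(array(rep(axis_ramp <- (0:20) * 2, 36), n), c(2, 2, 2))
  out <- resample_volume(ramp, 5.5)
  expected <- (seq_len(dim(out$values)[1]) - 1) * 5.5  # position in mm
  expect_equal(out$values[, 1, 1], expected, tolerance = 1e-10)
})

test_that("mask resampling preserves volume approximately and flags specks", {
  # Large centred cube: 56x56x56 mm at 2 mm spacing.
  m <- array(FALSE, c(41, 41, 41))
  m[6:33, 6:33, 6:33] <- TRUE
  mask <- roi_mask(m, c(2, 2, 2))
  out <- resample_mask(mask, 5.5)
  vol_phys <- sum(m) * 8
  expect_lt(abs(sum(out$values) * 5.5^3 - vol_phys) / vol_phys, 0.15)

  full <- roi_mask(array(TRUE, c(8, 8, 8)), c(2, 2, 2))
  expect_true(all(resample_mask(full, 5.5)$values))

  speck <- array(FALSE, c(15, 15, 15))
  speck[8, 8, 8] <- TRUE
  expect_warning(out <- resample_mask(roi_mask(speck, c(1, 1, 1)), 5.5), "empty")
  expect_true(attr(out, "empty"))
})

test_that("HU exclusion is inclusive at both bounds and matches enumeration", {
  m <- roi_mask(array(TRUE, c(3, 3, 3)), rep(5.5, 3))
  hu <- array(40, c(3, 3, 3))
  hu[1, 1, 1] <- 200      # boundary: retained
  hu[2, 1, 1] <- 200.1    # just above: removed
  hu[3, 1, 1] <- -300     # boundary: retained
  hu[1, 2, 1] <- -300.5   # just below: removed
  ct <- image_volume(hu, rep(5.5, 3), modality = "HU")
  out <- apply_hu_exclusion(m, ct)
  expect_true(out$values[1, 1, 1])
  expect_false(out$values[2, 1, 1])
  expect_true(out$values[3, 1, 1])
  expect_false(out$values[1, 2, 1])
  expect_equal(sum(out$values), 25)

  # Phantom bone insert: excluded count equals direct enumeration.
  ph <- generate_phantom(phantom_spec())
  excl <- apply_hu_exclusion(ph$mask, ph$ct)
  expect_equal(sum(ph$mask$values) - sum(excl$values),
               sum(ph$mask$values & ph$ct$values == 700))

  # Monotonicity: a narrower window never adds voxels.
  narrower <- apply_hu_exclusion(ph$mask, ph$ct, hu_min = -100, hu_max = 100)
  expect_true(all(excl$values | !narrower$values))

  expect_error(apply_hu_exclusion(m, image_volume(array(0, c(4, 4, 4)),
                                                  rep(5.5, 3))), "mismatch")
})

test_that("size gate uses an inclusive 72-voxel threshold", {
  make_mask <- function(k) {
    m <- array(FALSE, c(10, 10, 10))
    m[seq_len(k)] <- TRUE
    roi_mask(m, rep(5.5, 3))
  }
  expect_true(size_gate(make_mask(72)))
  expect_false(size_gate(make_mask(71)))
  expect_false(size_gate(make_mask(0)))
})

test_that("discretization follows the fixed-bin-size convention", {
  vol <- image_volume(array(c(0.30, 0.0, 0.25, 0.249, 1.0, 5.5, 0.5, 2),
                            c(2, 2, 2)), rep(5.5, 3))
  mask <- roi_mask(array(TRUE, c(2, 2, 2)), rep(5.5, 3))
  d <- discretize(vol, mask, 0.25)
  expect_equal(d$values[1, 1, 1], 2L)   # floor(0.30/0.25)+1
  expect_equal(d$values[2, 1, 1], 1L)   # 0 anchors to bin 1
  expect_equal(d$values[1, 2, 1], 2L)   # left-closed: 0.25 -> bin 2
  expect_equal(d$values[2, 2, 1], 1L)
  expect_equal(d$n_bins, max(d$values, na.rm = TRUE))

  # Scale consistency: scaling values and bin size by k leaves indices fixed.
  d2 <- discretize(image_volume(vol$values * 3, rep(5.5, 3)), mask, 0.75)
  expect_identical(d$values, d2$values)

  # Uniform ROI concentrates in a single bin.
  u <- discretize(image_volume(array(1.1, c(2, 2, 2)), rep(5.5, 3)), mask, 0.25)
  expect_equal(length(unique(u$values[!is.na(u$values)])), 1)

  neg <- image_volume(array(-0.1, c(2, 2, 2)), rep(5.5, 3))
  expect_warning(dn <- discretize(neg, mask, 0.25), "clamped")
  expect_true(all(dn$values == 1L))
})
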