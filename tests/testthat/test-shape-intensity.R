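test_that("volume and bounding box are exact voxel arithmetic", {
  m <- array(FALSE, c(10, 10, 10))
  m[m][] <- FALSE
  m[seq_len(72)] <- TRUE  # arbitrary 72-voxel blob in the first slab
  sf <- shape_features(roi_mask(m, rep(5.5, 3)))
  expect_equal(unname(sf["shape/mask/voxel_count"]), 72)
  expect_equal(unname(sf["shape/mask/volume_mm3"]), 72 * 166.375)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  sf1 <- shape_features(roi_mask(single, rep(5.5, 3)))
  expect_equal(unname(sf1[c("shape/mask/bbox_extent_x_mm",
                            "shape/mask/bbox_extent_y_mm",
                            "shape/mask/bbox_extent_z_mm")]),
               c(5.5, 5.5, 5.5))
  expect_error(shape_features(roi_mask(array(FALSE, c(3, 3, 3)), rep(1, 3))),
               "non-empty")
})

test_that("digital-ball sphericity approaches 1 as the radius grows", {
  ball_mask <- function(r) {
    n <- 2 * r + 9
    c0 <- (n - 1) / 2
    coords <- (0:(n - 1)) - c0
    d2 <- outer(outer(coords^2, coords^2, `+`), coords^2, `+`)
    roi_mask(d2 <= r^2, rep(1, 3))
  }
  s5 <- unname(shape_features(ball_mask(5))["shape/mask/sphericity"])
  s10 <- unname(shape_features(ball_mask(10))["shape/mask/sphericity"])
  expect_lt(abs(1 - s10), abs(1 - s5))
  expect_lt(abs(1 - s10), 0.05)
})

test_that("shape is intensity-free and principal axes see anisotropy", {
  m <- array(FALSE, c(12, 12, 12)); m[3:10, 4:9, 5:8] <- TRUE
  sf <- shape_features(roi_mask(m, rep(2, 3)))
  expect_gt(sf["shape/mask/major_axis_length_mm"],
            sf["shape/mask/least_axis_length_mm"])
  expect_lt(sf["shape/mask/elongation"], 1)
  expect_lt(sf["shape/mask/flatness"], sf["shape/mask/elongation"] + 1e-12)
})

test_that("intensity features match a formula-by-formula oracle", {
  x <- withr::with_seed(42, round(rlnorm(100, log(3), 0.4), 3))
  fv <- intensity_features(x, bin_size = 0.25)
  mu <- sum(x) / 100
  m2 <- sum((x - mu)^2) / 100
  expect_equal(unname(fv["intensity/suv/mean"]), mu)
  expect_equal(unname(fv["intensity/suv/variance"]), m2)
  expect_equal(unname(fv["intensity/suv/skewness"]),
               (sum((x - mu)^3) / 100) / m2^1.5)
  expect_equal(unname(fv["intensity/suv/kurtosis"]),
               (sum((x - mu)^4) / 100) / m2^2 - 3)
  expect_equal(unname(fv["intensity/suv/median"]), median(x))
  expect_equal(unname(fv["intensity/suv/minimum"]), min(x))
  expect_equal(unname(fv["intensity/suv/maximum"]), max(x))
  expect_equal(unname(fv["intensity/suv/range"]), max(x) - min(x))
  expect_equal(unname(fv["intensity/suv/percentile_10"]),
               unname(quantile(x, 0.1)))
  expect_equal(unname(fv["intensity/suv/percentile_90"]),
               unname(quantile(x, 0.9)))
  expect_equal(unname(fv["intensity/suv/interquartile_range"]),
               unname(quantile(x, 0.75) - quantile(x, 0.25)))
  expect_equal(unname(fv["intensity/suv/mean_absolute_deviation"]),
               mean(abs(x - mu)))
  expect_equal(unname(fv["intensity/suv/energy"]), sum(x^2))
  expect_equal(unname(fv["intensity/suv/root_mean_square"]),
               sqrt(mean(x^2)))
  expect_equal(unname(fv["intensity/suv/coefficient_of_variation"]),
               sqrt(m2) / mu)
  p <- table(floor(x / 0.25)) / 100
  expect_equal(unname(fv["intensity/suv/entropy"]), -sum(p * log2(p)))
  expect_equal(unname(fv["intensity/suv/uniformity"]), sum(p^2))
  expect_length(fv, 17)
})

test_that("intensity conventions: constants give 0, symmetry gives 0 skewness", {
  fv <- intensity_features(rep(2.5, 80))
  expect_equal(unname(fv["intensity/suv/mean"]), 2.5)
  expect_equal(unname(fv[c("intensity/suv/variance", "intensity/suv/skewness",
                           "intensity/suv/kurtosis",
                           "intensity/suv/coefficient_of_variation")]),
               rep(0, 4))
  sym <- intensity_features(rep(c(1, 3), 50))
  expect_equal(unname(sym["intensity/suv/skewness"]), 0)
})
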