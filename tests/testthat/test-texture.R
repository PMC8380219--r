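test_that("GLCM matches brute-force enumeration on random toy grids", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                c(-1, 1, 1), c(1, -1, 1))
  for (s in 1:5) {
    arr <- withr::with_seed(s, array(sample(0:4, 5^3, replace = TRUE), c(5, 5, 5)))
    if (all(arr == 0)) next
    d <- toy_droi(arr)
    for (k in seq_len(nrow(dirs))) {
      expect_equal(glcm_matrix(d, dirs[k, ])[seq_len(max(arr)), seq_len(max(arr))],
                   oracle_glcm(arr, dirs[k, ]),
                   info = sprintf("seed %d dir %s", s, paste(dirs[k, ], collapse = ",")))
    }
  }
})

test_that("GLCM contrast on a checkerboard matches hand-enumerated counts", {
  # 2x2x1-level checkerboard: along x every neighbour pair is (1,2) or (2,1).
  arr <- array(0L, c(4, 4, 1))
  arr[] <- ((row(arr[, , 1]) + col(arr[, , 1])) %% 2) + 1L
  d <- toy_droi(arr)
  M <- glcm_matrix(d, c(1, 0, 0))
  # 3 pairs per row, 4 rows, symmetric double counting -> 24 total.
  expect_equal(M, matrix(c(0, 12, 12, 0), 2, 2))
  P <- M / sum(M)
  feats <- petrad:::glcm_features(P)
  expect_equal(unname(feats["contrast"]), 1)        # |1-2|^2 everywhere
  expect_equal(unname(feats["joint_entropy"]), 1)   # two cells at 1/2
})

test_that("GLRLM and NGLDM match brute-force enumeration", {
  dirs <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1), c(-1, 1, 0))
  for (s in 1:5) {
    arr <- withr::with_seed(100 + s,
                            array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4)))
    if (sum(arr > 0) < 2) next
    d <- toy_droi(arr)
    for (k in seq_len(nrow(dirs))) {
      expect_equal(sort_triples(glrlm_counts(d, dirs[k, ])),
                   sort_triples(oracle_glrlm(arr, dirs[k, ])))
    }
    expect_equal(sort_triples(ngldm_counts(d)),
                 sort_triples(oracle_ngldm(arr)))
  }
})

test_that("GLSZM zones match hand-checked toy configurations", {
  arr <- array(0L, c(4, 4, 1))
  arr[1:2, 1:2, 1] <- 1L       # one 4-voxel zone of level 1
  arr[4, 4, 1] <- 1L           # isolated level-1 zone (diagonal not adjacent)
  arr[4, 1, 1] <- 2L           # single level-2 zone
  zones <- glszm_zones(toy_droi(arr))
  zones <- zones[order(zones$i, zones$size), ]
  expect_equal(zones$i, c(1L, 1L, 2L))
  expect_equal(sort(zones$size[zones$i == 1]), c(1L, 4L))
  expect_equal(zones$size[zones$i == 2], 1L)
  # All border voxels here have ROI-edge distance 1.
  expect_true(all(zones$distance == 1))
})

test_that("single-grey-level degenerate ROI follows the documented conventions", {
  arr <- array(1L, c(3, 3, 3))
  d <- toy_droi(arr)
  fv <- texture_features(d)
  expect_equal(unname(fv["texture/glcm_avg/joint_entropy"]), 0)
  expect_equal(unname(fv["texture/glcm_avg/correlation"]), 0)
  expect_equal(unname(fv["texture/glcm_avg/maximal_correlation_coefficient"]), 0)
  # NGLDM dependence-count entropy reduces to the entropy of the dependence
  # distribution alone.
  cc <- ngldm_counts(d)
  p <- cc$n / sum(cc$n)
  expect_equal(unname(fv["texture/ngldm/dependence_count_entropy"]),
               -sum(p * log2(p)))
  expect_true(all(is.finite(fv)))
})

test_that("normalized texture matrices sum to one and the roster holds 137", {
  ph <- generate_phantom(small_phantom())
  pc <- preprocess_case(ph$pet, ph$ct, ph$mask)
  d <- discretize(pc$pet, pc$mask, 0.25)
  for (dir in list(c(1, 0, 0), c(1, 1, 1))) {
    M <- glcm_matrix(d, dir)
    expect_equal(sum(M / sum(M)), 1, tolerance = 1e-9)
  }
  cc <- glrlm_counts(d, c(0, 1, 0))
  expect_equal(sum(cc$n / sum(cc$n)), 1, tolerance = 1e-9)
  fv <- texture_features(d)
  expect_length(fv, 137)
  expect_true(all(is.finite(fv)))
  pref <- sub("^texture/([a-z_]+)/.*$", "\\1", names(fv))
  cnt <- table(pref)[c("glcm_avg", "glcm_mrg", "glrlm_avg", "glrlm_mrg",
                       "glszm", "gldzm", "ngtdm", "ngldm")]
  expect_equal(as.integer(cnt), c(26L, 25L, 16L, 16L, 16L, 16L, 5L, 17L))
})
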