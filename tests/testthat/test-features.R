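# Hand-worked and degenerate cases per texture class; bulk random-ROI
# equivalence against the brute-force oracles lives in test-acceptance.R.

test_that("first-order features match closed forms on tiny inputs", {
  v <- matrix(1:10, 2, 5)
  f <- first_order_features(image_slice(v, c(1, 1)), matrix(TRUE, 2, 5))
  expect_equal(f[["Mean"]], 5.5)
  expect_equal(f[["Median"]], 5.5)
  expect_equal(f[["Range"]], 9)
  expect_equal(f[["10Percentile"]], 1.9)
  fc <- first_order_features(image_slice(matrix(4, 3, 4), c(1, 1)),
                             matrix(TRUE, 3, 4))
  expect_equal(fc[["Energy"]], 12 * 16)
  expect_equal(fc[["Variance"]], 0)
  expect_equal(fc[["Entropy"]], 0)
  expect_equal(fc[["Uniformity"]], 1)
  expect_equal(fc[["Skewness"]], 0)
  expect_equal(fc[["Kurtosis"]], 0)
})

test_that("GLCM on a hand-enumerated 2x2 grid", {
  L <- matrix(c(1L, 2L, 1L, 2L), 2, 2)   # rows: (1,1) / (2,2)
  f <- glcm_features(L, 2, angles = 0)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["MaximumProbability"]], 0.5)
  expect_equal(f[["JointEnergy"]], 0.5)
  fc <- glcm_features(matrix(1L, 3, 3), 1)
  expect_equal(fc[["JointEnergy"]], 1)
  expect_equal(fc[["JointEntropy"]], 0)
  expect_equal(fc[["Correlation"]], 1)
})

test_that("GLRLM on hand-enumerated runs", {
  L <- matrix(c(1L, 1L, 1L, 2L), 1, 4)
  f <- glrlm_features(L, 2, angles = 0)
  expect_equal(f[["RunPercentage"]], 0.5)   # 2 runs / 4 pixels
  Lc <- matrix(1L, 1, 5)
  fc <- glrlm_features(Lc, 1, angles = 0)
  expect_equal(fc[["LongRunEmphasis"]], 25)
  expect_equal(fc[["RunEntropy"]], 0)
})

test_that("GLSZM zones follow 8-connectivity", {
  fc <- glszm_features(matrix(1L, 3, 3), 1)
  expect_equal(fc[["ZonePercentage"]], 1 / 9)  # one zone of size 9
  expect_equal(fc[["LargeAreaEmphasis"]], 81)
  cb <- outer(1:4, 1:4, function(r, c_) ((r + c_) %% 2) + 1L)
  z <- strokesep:::label_zones(cb)
  expect_equal(nrow(z), 2)            # diagonals connect each colour
  expect_true(all(z$size == 8))
})

test_that("GLDM dependence counts on a uniform patch", {
  f <- gldm_features(matrix(1L, 3, 3), 1)
  # centre pixel has 8 dependent neighbours (size 9), edges 5+1, corners 3+1
  expect_equal(f[["LargeDependenceEmphasis"]],
               (4 * 4^2 + 4 * 6^2 + 1 * 9^2) / 9)
  expect_equal(f[["GrayLevelNonUniformity"]], 9)
})

test_that("NGTDM is zero-contrast on a uniform patch", {
  f <- ngtdm_features(matrix(1L, 4, 4), 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Coarseness"]], 1e6)
  ck <- outer(1:4, 1:4, function(r, c_) ((r + c_) %% 2) + 1L)
  fo <- oracle_ngtdm(ck, 2)
  expect_equal(ngtdm_features(ck, 2), fo, tolerance = 1e-12)
})

test_that("GLCM normalization sums to one per angle", {
  for (s in 1:10) {
    rl <- random_levels(s)
    for (o in list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
      P <- strokesep:::glcm_matrix(rl$levels, rl$ng, o[1], o[2])
      if (sum(P) > 0) expect_equal(sum(P), 1, tolerance = 1e-12)
    }
  }
})

test_that("discretized-matrix features are shift invariant, Mean equivariant", {
  h <- generate_head_slice(quiet_spec(), seed = 6)
  m <- tiny_mask(160, 160, 80, 55)
  cfg <- extract_config(transforms = "original")
  f1 <- extract_all(h$slice, m, cfg)
  f2 <- extract_all(image_slice(h$slice$values + 50, h$slice$spacing), m, cfg)
  expect_equal(f2[["original_firstorder_Mean"]],
               f1[["original_firstorder_Mean"]] + 50)
  glcm_names <- grep("_glcm_", names(f1), value = TRUE)
  expect_equal(f1[glcm_names], f2[glcm_names], tolerance = 1e-9)
  glrlm_names <- grep("_glrlm_", names(f1), value = TRUE)
  expect_equal(f1[glrlm_names], f2[glrlm_names], tolerance = 1e-9)
})
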