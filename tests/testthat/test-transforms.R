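test_that("original transform is the identity", {
  h <- generate_head_slice(quiet_spec(), seed = 1)
  m <- tiny_mask(160, 160, 80, 55)
  out <- apply_transform(h$slice, m, "original")
  expect_identical(out$values, h$slice$values)
  expect_error(apply_transform(h$slice, m, "no_such"), "unknown")
})

test_that("wavelet detail subbands vanish on constant images", {
  v <- matrix(5, 32, 32)
  m <- tiny_mask()
  for (k in c("wavelet_LH", "wavelet_HL", "wavelet_HH")) {
    out <- apply_transform(v, m, k, rescale = FALSE)
    expect_equal(max(abs(out$values[m])), 0)
  }
  ll <- apply_transform(v, m, "wavelet_LL", rescale = FALSE)
  expect_equal(unique(c(ll$values)), 10)  # orthonormal Haar doubles constants
})

test_that("pointwise transforms follow the shift-normalize arithmetic", {
  set.seed(3)
  v <- matrix(rnorm(64, -40, 20), 8, 8)
  m <- matrix(TRUE, 8, 8)
  s <- v - min(v) + 1
  s <- s / max(s)
  sq <- apply_transform(v, m, "square", rescale = FALSE)
  for (px in c(1L, 17L, 64L)) expect_equal(sq$values[px], s[px]^2)
  expect_equal(apply_transform(v, m, "squareroot", rescale = FALSE)$values,
               sqrt(s))
  expect_equal(apply_transform(v, m, "logarithm", rescale = FALSE)$values,
               log(s))
  expect_equal(apply_transform(v, m, "exponential", rescale = FALSE)$values,
               exp(s))
  resc <- apply_transform(v, m, "square", rescale = TRUE)
  expect_equal(range(resc$values[m]), range(v[m]))
})

test_that("gradient magnitude matches central differences", {
  v <- outer(1:10, 1:10, function(r, c_) 3 * r + 4 * c_)
  g <- apply_transform(image_slice(v, c(1, 1)), matrix(TRUE, 10, 10),
                       "gradient", rescale = FALSE)
  expect_equal(g$values[5, 5], 5)  # interior gradient of 3y + 4x
})

test_that("fixed-bin-width discretization maps arithmetic levels", {
  v <- matrix(c(0, 5, 10, 15), 2, 2)
  d <- discretize(v, matrix(TRUE, 2, 2), mode = "fixed_bin_width",
                  bin_width = 5)
  expect_identical(sort(unique(c(d$levels))), 1:4)
  expect_identical(d$ng, 4L)
  dc <- discretize(matrix(7, 3, 3), matrix(TRUE, 3, 3))
  expect_identical(dc$ng, 1L)
  expect_true(all(dc$levels == 1))
})

test_that("fixed-bin-count discretization agrees with an independent binning", {
  set.seed(11)
  v <- matrix(runif(100, -50, 70), 10, 10)
  m <- matrix(runif(100) > 0.3, 10, 10)
  d <- discretize(v, m, mode = "fixed_bin_count", bin_count = 8)
  expect_lte(d$ng, 8L)
  vals <- v[m]
  ref <- cut(vals, breaks = seq(min(vals), max(vals), length.out = 9),
             include.lowest = TRUE, labels = FALSE)
  expect_identical(as.integer(d$levels[m]), as.integer(ref))
})

test_that("extraction is mask-restricted beyond the padded bounding box", {
  h <- generate_head_slice(quiet_spec(), seed = 2)
  m <- tiny_mask(160, 160, 80, 55)
  f1 <- extract_all(h$slice, m)
  v2 <- h$slice$values
  v2[10, 10] <- 999   # far outside the padded bbox
  f2 <- extract_all(image_slice(v2, h$slice$spacing), m)
  expect_identical(f1, f2)
})

test_that("the registry is fixed-order, complete, and reproducible", {
  cfg <- extract_config()
  reg <- feature_registry(cfg)
  expect_length(reg, 930)
  expect_identical(reg, feature_registry(extract_config()))
  small <- extract_config(transforms = "original", classes = "firstorder")
  expect_length(feature_registry(small), 18)
  h <- generate_head_slice(quiet_spec(), seed = 3)
  m <- tiny_mask(160, 160, 80, 55)
  fv <- extract_all(h$slice, m, small)
  expect_identical(names(fv), feature_registry(small))
  expect_identical(extract_all(h$slice, m, small), fv)
})
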