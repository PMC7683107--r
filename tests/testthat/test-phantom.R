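test_that("noise-free jitter-free phantom is exactly mirror symmetric", {
  h <- generate_head_slice(quiet_spec(), seed = 1)
  v <- h$slice$values
  expect_equal(v, v[, ncol(v):1], tolerance = 0)
  expect_true(all(is.finite(v)))
})

test_that("head generation is deterministic per seed and rejects bad shapes", {
  a <- generate_head_slice(small_spec(), seed = 11)
  b <- generate_head_slice(small_spec(), seed = 11)
  expect_identical(a$slice$values, b$slice$values)
  c_ <- generate_head_slice(small_spec(), seed = 12)
  expect_false(identical(a$slice$values, c_$slice$values))
  expect_error(phantom_spec(image_shape = c(0, 64)), "positive")
  expect_error(phantom_spec(tissue_means = c(background = 10, skull = 5,
                                             white = 2, gray = 3)), "ordered")
})

test_that("noise field inside the brain has the requested SD", {
  s0 <- generate_head_slice(quiet_spec(), seed = 2)
  sn <- generate_head_slice(small_spec(noise_sd = 5, noise_corr_len = 2,
                                       asymmetry_jitter = 0), seed = 2)
  sd_obs <- sd((sn$slice$values - s0$slice$values)[s0$brain])
  expect_lt(abs(sd_obs - 5) / 5, 0.15)
})

test_that("zero-irregularity lesion is a rasterized disk; seeds vary blobs", {
  h <- generate_head_slice(quiet_spec(), seed = 1)
  sp <- lesion_spec(center = c(80, 55), mean_radius = 10,
                    boundary_irregularity = 0, seed = 1)
  m <- sample_lesion_roi(h$brain, sp)
  # exact rasterized disk: pixel centres within mean_radius of the centre
  nr <- nrow(m); nc <- ncol(m)
  d <- sqrt(outer((1:nr - 80)^2, (1:nc - 55)^2, "+"))
  expect_identical(m, d <= 10)
  m1 <- sample_lesion_roi(h$brain, lesion_spec(center = c(80, 55),
                                               mean_radius = 10, seed = 5))
  m2 <- sample_lesion_roi(h$brain, lesion_spec(center = c(80, 55),
                                               mean_radius = 10, seed = 6))
  expect_false(identical(m1, m2))
})

test_that("irregular blob areas respect the factor-of-two contract", {
  h <- generate_head_slice(quiet_spec(shape = c(256, 256)), seed = 1)
  areas <- vapply(1:100, function(s) {
    m <- sample_lesion_roi(h$brain,
                           lesion_spec(center = c(128, 88), mean_radius = 15,
                                       boundary_irregularity = 0.3, seed = s))
    sum(m)
  }, 0)
  expect_true(all(areas >= pi * 15^2 / 2))
  expect_true(all(areas <= 2 * pi * 15^2))
})

test_that("lesions crossing the midline or leaving the brain are rejected", {
  h <- generate_head_slice(quiet_spec(), seed = 1)
  mid <- lesion_spec(center = c(80, 80), mean_radius = 10,
                     boundary_irregularity = 0)
  expect_error(sample_lesion_roi(h$brain, mid), "midline")
  out <- lesion_spec(center = c(80, 30), mean_radius = 12,
                     boundary_irregularity = 0)
  expect_error(sample_lesion_roi(h$brain, out), "brain")
})

test_that("lesion injection is identity at zero effect and local otherwise", {
  h <- generate_head_slice(small_spec(), seed = 3)
  m <- sample_lesion_roi(h$brain, lesion_spec(center = c(80, 55),
                                              mean_radius = 10, seed = 2))
  null_spec <- lesion_spec(center = c(80, 55), delta_hu = 0, smooth_sigma = 0)
  expect_identical(inject_lesion(h$slice, m, null_spec)$values,
                   h$slice$values)
  eff <- inject_lesion(h$slice, m, lesion_spec(center = c(80, 55),
                                               delta_hu = -6,
                                               smooth_sigma = 1.5))
  expect_equal(mean(eff$values[m]) - mean(h$slice$values[m]), -6,
               tolerance = 1)
  expect_identical(eff$values[!m], h$slice$values[!m])
  smoothed <- inject_lesion(h$slice, m,
                            lesion_spec(center = c(80, 55), delta_hu = 0,
                                        smooth_sigma = 2))
  expect_lt(var(smoothed$values[m]), var(h$slice$values[m]))
  expect_error(inject_lesion(h$slice, m[60:100, 40:70],
                             lesion_spec(center = c(5, 5))), "shape")
})

test_that("mean-shift contract holds in expectation over many seeds", {
  shifts <- vapply(1:50, function(s) {
    h <- generate_head_slice(small_spec(), seed = s)
    m <- sample_lesion_roi(h$brain,
                           lesion_spec(center = c(80, 55), mean_radius = 10,
                                       boundary_irregularity = 0.3, seed = s))
    sp <- lesion_spec(center = c(80, 55), delta_hu = -6, smooth_sigma = 1.5)
    out <- inject_lesion(h$slice, m, sp)
    mean(out$values[m]) - mean(h$slice$values[m])
  }, 0)
  se <- sd(shifts) / sqrt(length(shifts))
  expect_lt(abs(mean(shifts) - (-6)), 2 * se + 1e-8)
})

test_that("cohort bookkeeping matches the one/three-slice design", {
  co <- generate_cohort(2, 1, small_spec(), small_dist(), seed = 5)
  groups <- vapply(co$subjects, `[[`, "", "group")
  expect_identical(groups, c("lesion", "lesion", "normal"))
  nsl <- vapply(co$subjects, function(s) length(s$slices), 0L)
  expect_identical(nsl, c(1L, 1L, 3L))
  for (sub in co$subjects) for (rec in sub$slices) {
    expect_gt(sum(rec$mask), 0)
    expect_true(all(rec$brain[rec$mask]))
  }
  co2 <- generate_cohort(2, 1, small_spec(), small_dist(), seed = 5)
  expect_identical(co$subjects[[1]]$slices[[1]]$slice$values,
                   co2$subjects[[1]]$slices[[1]]$slice$values)
  expect_identical(co$subjects[[3]]$slices[[2]]$mask,
                   co2$subjects[[3]]$slices[[2]]$mask)
})
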