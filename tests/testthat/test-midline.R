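test_that("midline of a symmetric phantom is the centre vertical", {
  h <- generate_head_slice(quiet_spec(), seed = 1)
  ml <- estimate_midline(h$slice, h$brain)
  expect_identical(ml$offset, 0)
  expect_identical(ml$angle, 0)
})

test_that("midline recovers known rotations and shifts", {
  h <- generate_head_slice(small_spec(shape = c(256, 256)), seed = 4)
  rot <- warp_affine(h$slice$values, affine_params(theta = -4), fill = -1000)
  rb <- warp_affine(h$brain * 1, affine_params(theta = -4),
                    interp = "nearest", fill = 0) > 0.5
  ml <- estimate_midline(rot, rb)
  expect_lt(abs(ml$angle - 4), 1.01)
  sh <- warp_affine(h$slice$values, affine_params(tx = 10), fill = -1000)
  sb <- warp_affine(h$brain * 1, affine_params(tx = 10),
                    interp = "nearest", fill = 0) > 0.5
  ml2 <- estimate_midline(sh, sb)
  expect_lt(abs(ml2$offset - 10), 1.01)
  tiny <- matrix(FALSE, 160, 160); tiny[80, 1:50] <- TRUE
  expect_error(estimate_midline(h$slice, tiny), "degenerate")
})

test_that("midline estimator is unbiased on symmetric noisy phantoms", {
  offs <- vapply(1:25, function(s) {
    h <- generate_head_slice(small_spec(asymmetry_jitter = 0), seed = s)
    estimate_midline(h$slice, h$brain, max_points = 6000)$offset
  }, 0)
  expect_lte(mean(abs(offs)), 1)
})

test_that("mirroring is an involution that preserves area and centroids", {
  set.seed(7)
  h <- generate_head_slice(quiet_spec(), seed = 2)
  for (s in 1:10) {
    m <- sample_lesion_roi(h$brain,
                           lesion_spec(center = c(75 + s, 55),
                                       mean_radius = 8 + (s %% 4),
                                       boundary_irregularity = 0.25,
                                       seed = s))
    ml <- midline_params(offset = (s %% 5) - 2, angle = (s %% 7) / 2 - 1.5)
    mr <- mirror_roi(m, ml)
    expect_lte(abs(sum(mr) - sum(m)) / sum(m), 0.02)
    back <- mirror_roi(mr, ml)
    expect_gte(2 * sum(back & m) / (sum(back) + sum(m)), 0.95)
    c0 <- mask_centroid(m)
    rf <- strokesep:::reflect_xy(c0["x"], c0["y"], ml, dim(m))
    c1 <- mask_centroid(mr)
    expect_lt(abs(c1["x"] - rf$x), 1)
    expect_lt(abs(c1["y"] - rf$y), 1)
  }
})

test_that("mask symmetric about the line is a mirror fixed point", {
  m <- matrix(FALSE, 40, 40)
  m[15:25, 16:24] <- TRUE   # symmetric about column x = 19 (0-based)
  ml <- midline_params(offset = 19 - 19.5, angle = 0)
  expect_identical(mirror_roi(m, ml), m)
  expect_error(mirror_roi(tiny_mask(), midline_params(offset = 40)),
               "leaves the image")
})

test_that("candidate pairs carry labels, pairings, and disjoint mirrors", {
  co <- generate_cohort(2, 1, small_spec(), small_dist(), seed = 9)
  les <- co$subjects[[1]]
  pairs <- make_candidate_pairs(les)
  expect_length(pairs, 1)
  expect_identical(vapply(pairs[[1]], `[[`, "", "label"),
                   c("lesion", "mirror"))
  expect_identical(pairs[[1]][[1]]$pairing_id, pairs[[1]][[2]]$pairing_id)
  expect_equal(sum(pairs[[1]][[1]]$mask & pairs[[1]][[2]]$mask), 0)
  norm <- co$subjects[[3]]
  npairs <- make_candidate_pairs(norm)
  expect_length(npairs, 3)
  expect_identical(vapply(npairs[[2]], `[[`, "", "label"),
                   c("normal", "normal_mirror"))
})
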