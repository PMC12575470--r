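test_that("affine poses transform points and round-trip through their inverse", {
  expect_equal(transform_point(affine_pose(), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(transform_point(pose_translation(c(10, 0, 0)), c(1, 2, 3)),
               c(11, 2, 3))
  set.seed(42)
  pose <- pose_compose(pose_translation(runif(3, -50, 50)),
                       pose_rotation("z", runif(1, 0, 360)),
                       pose_rotation("x", runif(1, 0, 360)))
  for (i in 1:20) {
    p <- runif(3, -100, 100)
    expect_equal(transform_point(pose, transform_point(pose, p), inverse = TRUE),
                 p, tolerance = 1e-9)
  }
  singular <- diag(4); singular[1, 1] <- 0
  expect_error(affine_pose(singular), "singular")
})

test_that("volume and mask constructors enforce their invariants", {
  expect_error(scalar_volume(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(scalar_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(segmentation_mask(array(300L, c(2, 2, 2))), "\\[0, 255\\]")
  v <- scalar_volume(array(0, c(4, 5, 6)))
  m <- segmentation_mask(dims = c(4, 5, 5))
  tf <- tf_opaque()
  expect_error(volume_node(v, tf, mask = m), "match")
})

test_that("trilinear sampling is exact on lattice points and midpoints", {
  v <- coord_volume()
  expect_equal(sample_intensity(v, c(2, 3, 4)), 2 + 30 + 400)
  expect_equal(sample_intensity(v, c(0.5, 0, 0)), 0.5)  # 0 and 1 midway
  # clamped outside the grid
  expect_equal(sample_intensity(v, c(-3, 0, 0)), 0)
  expect_equal(sample_intensity(v, c(10, 4, 4)), 4 + 40 + 400)
})

test_that("trilinear sampling matches the 8-corner weighted-sum oracle and is bounded by corners", {
  set.seed(7)
  data <- array(runif(5 * 6 * 7, -50, 900), c(5, 6, 7))
  v <- scalar_volume(data)
  for (i in 1:50) {
    p <- runif(3, -0.5, 1) * (dim(data) - 1)
    got <- sample_intensity(v, p)
    expect_equal(got, trilinear_oracle(data, p), tolerance = 1e-12)
    pc <- pmin(pmax(p, 0), dim(data) - 1)
    lo <- pmax(floor(pc), 0) + 1
    hi <- pmin(lo + 1, dim(data))
    corners <- data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    expect_gte(got, min(corners) - 1e-9)
    expect_lte(got, max(corners) + 1e-9)
  }
})

test_that("label sampling is nearest-neighbor and 0 outside the grid", {
  m <- segmentation_mask(dims = c(4, 4, 4))
  m$labels[2, 3, 4] <- 7L
  expect_equal(sample_label(m, c(1, 2, 3)), 7L)       # exact center
  expect_equal(sample_label(m, c(1.4, 2.4, 2.6)), 7L) # still nearest
  expect_equal(sample_label(m, c(1.6, 2, 3)), 0L)     # nearer neighbor wins
  expect_equal(sample_label(m, c(-1, 0, 0)), 0L)
  expect_equal(sample_label(m, c(0, 0, 9)), 0L)
})

test_that("classification clamps, hides segments, and applies the step-size opacity correction", {
  tf <- transfer_function(c(100, 200),
                          rbind(c(1, 0, 0, 0), c(1, 0, 0, 0.5)),
                          segment_opacity = c("3" = 0),
                          reference_step = 1)
  expect_equal(unname(classify(tf, 50, step = 1)[, "a"]), 0)          # clamp below
  expect_equal(unname(classify(tf, 500, 3, step = 1)[, "a"]), 0)      # hidden label
  expect_equal(unname(classify(tf, 500, step = 2)[, "a"]), 1 - 0.5^2) # alpha' = 0.75
  expect_equal(unname(classify(tf, 500, step = 1)[, "a"]), 0.5)       # ref step: unchanged
  # monotone in segment opacity
  a <- vapply(seq(0, 1, by = 0.1), function(m) {
    classify(set_segment_opacity(tf, 5L, m), 500, 5L, step = 1)[, "a"]
  }, 0)
  expect_true(all(diff(a) >= 0))
  expect_error(transfer_function(c(1, 1), rbind(c(0, 0, 0, 0), c(0, 0, 0, 1))),
               "strictly increasing")
})

test_that("constant-interpolation transfer functions are exactly binary", {
  tf <- tf_opaque(threshold = 300)
  a <- classify(tf, seq(-500, 1200, by = 7), step = 0.37)[, "a"]
  expect_true(all(a %in% c(0, 1)))
  expect_identical(a, as.numeric(seq(-500, 1200, by = 7) >= 300))
})
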