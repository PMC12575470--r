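test_that("sphere painting labels exactly the voxel centers within the radius", {
  m <- segmentation_mask(dims = c(20, 20, 20))
  # radius enclosing exactly one voxel center
  m1 <- paint_sphere(m, center = c(10, 10, 10), radius = 0.6, label = 3L)
  expect_equal(sum(m1$labels == 3L), 1L)
  expect_equal(m1$labels[11, 11, 11], 3L)
  # brute-force count at a fractional center / larger radius
  ctr <- c(7.3, 11.2, 9.8); rad <- 4.7
  m2 <- paint_sphere(m, ctr, rad, 5L)
  g <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  want <- sum(rowSums(sweep(g, 2, ctr)^2) <= rad^2)
  expect_equal(sum(m2$labels == 5L), want)
  # painting respects a non-identity pose (world-space brush)
  pose <- pose_translation(c(100, 0, 0))
  m3 <- paint_sphere(m, c(110, 10, 10), 0.6, 9L, pose = pose)
  expect_equal(which(m3$labels == 9L), which(m1$labels == 3L))
  # overwriting and the reserved label
  m4 <- paint_sphere(m2, ctr, rad, 2L)
  expect_equal(sum(m4$labels == 5L), 0L)
  expect_equal(sum(m4$labels == 2L), want)
  expect_error(paint_sphere(m, ctr, rad, 0L), "reserved")
})

test_that("segment bounding boxes are tight and match a brute-force scan", {
  m <- segmentation_mask(dims = c(16, 16, 16))
  m$labels[5, 7, 9] <- 4L
  bb <- segment_aabb(m, 4L)
  expect_equal(bb$lo, c(4L, 6L, 8L))
  expect_equal(bb$hi, c(4L, 6L, 8L))
  expect_error(segment_aabb(m, 13L), "absent")
  set.seed(21)
  for (trial in 1:5) {
    mm <- segmentation_mask(
      array(sample(0:3, 16^3, replace = TRUE, prob = c(0.9, 0.04, 0.03, 0.03)),
            c(16, 16, 16)))
    for (lb in 1:3) {
      bb <- segment_aabb(mm, lb)
      idx <- which(mm$labels == lb, arr.ind = TRUE) - 1L
      expect_equal(bb$lo, as.integer(apply(idx, 2, min)))
      expect_equal(bb$hi, as.integer(apply(idx, 2, max)))
    }
  }
})

test_that("extraction copies the segment data, hides it in the source, and appends one node", {
  ps <- phantom_scene("keyhole_skull", seed = 0, image_size = c(64, 64))
  sc <- ps$scene
  expect_length(sc$nodes, 1L)
  sc2 <- extract_segment(sc, 1L, 1L, pad = 1L)
  expect_length(sc2$nodes, 2L)
  src <- sc2$nodes[[1]]
  new <- sc2$nodes[[2]]
  expect_equal(new$creation_index, 2L)
  # the segment is hidden from the source, visible in the new node
  expect_equal(src$tf$segment_opacity[1L + 1L], 0)
  expect_equal(new$tf$segment_opacity[1L + 1L], 1)
  expect_equal(new$tf$segment_opacity[0L + 1L], 0)  # non-segment voxels hidden
  # every extracted voxel equals the corresponding source voxel
  bb <- segment_aabb(src$mask, 1L)
  lo <- pmax(bb$lo - 1L, 0L); hi <- pmin(bb$hi + 1L, src$volume$dims - 1L)
  expect_identical(new$volume$data,
                   src$volume$data[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L,
                                   (lo[3]:hi[3]) + 1L])
  expect_true(all(new$mask$labels %in% c(0L, 1L)))
  # in-place pose: voxel (0,0,0) of the new node maps to source voxel `lo`
  expect_equal(transform_point(new$pose, c(0, 0, 0)),
               transform_point(src$pose, lo * src$volume$spacing),
               tolerance = 1e-12)
})

test_that("extraction leaves the rendered image essentially unchanged (conservation)", {
  ps <- phantom_scene("keyhole_skull", seed = 0, image_size = c(64, 64))
  pre <- render_scene(ps$scene, ps$camera, render_params())
  sc2 <- extract_segment(ps$scene, 1L, 1L)
  post <- render_scene(sc2, ps$camera, render_params())
  dp <- diff_pixel_mask(pre, post)
  expect_gte(mean(!dp), 0.99)
  if (any(dp)) {
    seg_only <- render_scene(scene(sc2$nodes[[2]]), ps$camera, render_params())
    sil <- seg_only$alpha > 0
    edge <- dilate1(sil) & dilate1(!sil)
    expect_true(all(dp[!dilate1(edge)] == FALSE))
  }
})

test_that("extracting all k segments yields k + 1 scene nodes", {
  ps <- phantom_scene("fracture", seed = 2, dims = c(48, 48, 48))
  sc <- extract_all_segments(ps$scene, 1L)
  expect_length(sc$nodes, 6L)
  expect_equal(vapply(sc$nodes, function(n) n$creation_index, 0L), 1:6)
  # the source now hides all five fragments
  expect_true(all(sc$nodes[[1]]$tf$segment_opacity[2:6] == 0))
})
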