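test_that("camera rays are unit length, hit the image center, and match the vfov geometry", {
  cam <- test_camera(image_size = c(65, 65), vfov = 50)
  r <- generate_ray(cam, c(32, 32))  # center pixel of an odd-sized image
  expect_equal(r$direction, cam$forward, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:25) {
    px <- c(sample(0:64, 1), sample(0:64, 1))
    d <- generate_ray(cam, px)$direction
    expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-12)
  }
  # top-center pixel: angle to forward = atan(tan(vfov/2) * (h-1)/h)
  h <- 65
  rt <- generate_ray(cam, c(32, 0))
  ang <- acos(sum(rt$direction * cam$forward))
  expect_equal(ang, atan(tan(50 / 2 * pi / 180) * (h - 1) / h),
               tolerance = 1e-9)
  expect_error(generate_ray(cam, c(65, 0)), "outside")
})

test_that("ray/AABB slab intersection handles hits, misses, and origins inside the box", {
  ray <- structure(list(origin = c(0, 0, 0), direction = c(1, 0, 0),
                        t_near = 0.01, t_far = 100), class = "voxray_ray")
  expect_equal(unname(intersect_ray_aabb(ray, c(2, -1, -1), c(3, 1, 1))),
               c(2, 3))
  expect_null(intersect_ray_aabb(ray, c(2, 2, -1), c(3, 3, 1)))
  # origin inside: entry clamped to t_near
  expect_equal(unname(intersect_ray_aabb(ray, c(-1, -1, -1), c(1, 1, 1))),
               c(0.01, 1))
  # parallel ray outside a slab
  ray2 <- structure(list(origin = c(0, 5, 0), direction = c(1, 0, 0),
                         t_near = 0.01, t_far = 100), class = "voxray_ray")
  expect_null(intersect_ray_aabb(ray2, c(2, -1, -1), c(3, 1, 1)))
})

test_that("marching a fully transparent or clamped-away volume yields no output", {
  v <- flat_volume(700)
  tf0 <- transfer_function(c(0, 1000), rbind(c(1, 1, 1, 0), c(1, 1, 1, 0)))
  node <- volume_node(v, tf0, pose = pose_translation(c(-8, -8, -8)))
  cam <- test_camera()
  ray <- generate_ray(cam, c(32, 32))
  out <- march_single(ray, node, render_params(step = 0.5))
  expect_equal(out$rgba, c(0, 0, 0, 0))
  expect_null(out$hit)
  # opaque volume but t_clamp at t_near: nothing marched
  node2 <- volume_node(v, tf_opaque(), pose = pose_translation(c(-8, -8, -8)))
  out2 <- march_single(ray, node2, render_params(step = 0.5),
                       t_clamp = ray$t_near)
  expect_equal(out2$rgba, c(0, 0, 0, 0))
  expect_null(out2$hit)
})

test_that("a binary opaque volume returns the TF color and the first sample distance", {
  v <- flat_volume(700)
  node <- volume_node(v, tf_opaque(color = c(0.2, 0.4, 0.8)),
                      pose = pose_translation(c(-8, -8, -8)))
  cam <- test_camera()
  ray <- generate_ray(cam, c(32, 32))
  out <- march_single(ray, node, render_params(step = 0.5))
  expect_equal(out$rgba, c(0.2, 0.4, 0.8, 1))
  # local box [-0.5, 15.5] shifted by -8: world box [-8.5, 7.5]^3; the
  # first sample sits half a step past the entry point of this ray
  seg <- intersect_ray_aabb(ray, rep(-8.5, 3), rep(7.5, 3))
  expect_equal(out$hit, unname(seg[1]) + 0.25, tolerance = 1e-9)
})

test_that("homogeneous-slab accumulation matches the closed-form transmittance", {
  v <- flat_volume(500, dims = c(41L, 16L, 16L))
  alpha <- 0.3
  node <- volume_node(v, tf_constant_alpha(alpha),
                      pose = pose_translation(c(-60.25, -8, -8)))
  cam <- test_camera(eye = c(100, 0, 0), far = 1000)
  ray <- generate_ray(cam, c(32, 32))
  for (step in c(1, 0.5, 0.25)) {
    out <- march_single(ray, node, render_params(step = step, alpha_threshold = 1))
    # count samples the marcher takes inside [t_enter, t_exit)
    seg <- intersect_ray_aabb(
      structure(list(origin = ray$origin - c(0, 0, 0),
                     direction = ray$direction,
                     t_near = ray$t_near, t_far = ray$t_far),
                class = "voxray_ray"),
      transform_point(node$pose, c(-0.5, -0.5, -0.5)),
      transform_point(node$pose, c(40.5, 15.5, 15.5)))
    n <- sum(seg[1] + (seq_len(1e5) - 0.5) * step < seg[2])
    a_step <- 1 - (1 - alpha)^step
    expect_equal(out$rgba[4], 1 - (1 - a_step)^n, tolerance = 1e-9)
  }
})

test_that("accumulated opacity converges under step refinement (transmittance limit)", {
  v <- flat_volume(500, dims = c(41L, 16L, 16L))
  alpha <- 0.4
  node <- volume_node(v, tf_constant_alpha(alpha),
                      pose = pose_translation(c(-60.25, -8, -8)))
  cam <- test_camera(eye = c(100, 0, 0), far = 1000)
  ray <- generate_ray(cam, c(32, 32))
  L <- 41  # slab length along the ray (mm)
  limit <- 1 - (1 - alpha)^L  # opacity-corrected invariant
  a_coarse <- march_single(ray, node, render_params(step = 1, alpha_threshold = 1))$rgba[4]
  a_fine <- march_single(ray, node, render_params(step = 0.125, alpha_threshold = 1))$rgba[4]
  expect_lt(abs(a_fine - limit), abs(a_coarse - limit) + 1e-12)
  expect_lt(abs(a_fine - limit), 0.01)
})

test_that("premultiplied accumulation is bounded and color never exceeds opacity", {
  s <- random_blob_scene(3, seed = 5, image_size = c(48, 48))
  # semi-transparent variant of the same scene
  for (i in seq_along(s$scene$nodes))
    s$scene$nodes[[i]]$tf <- transfer_function(
      c(150, 400), rbind(c(0.9, 0.5, 0.2, 0), c(0.9, 0.5, 0.2, 0.35)))
  r <- render_scene(s$scene, s$camera, render_params(alpha_threshold = 1))
  expect_true(all(r$alpha >= 0 & r$alpha <= 1 + 1e-12))
  for (ch in 1:3) {
    sc_node <- scene(s$scene$nodes[[1]])
    expect_true(all(r$color[, , ch] >= -1e-12))
  }
})

test_that("empty-space skipping never changes the image", {
  ps <- phantom_scene("keyhole_skull", seed = 3, image_size = c(64, 64))
  on <- render_scene(ps$scene, ps$camera, render_params(skip = TRUE, block_size = 4))
  off <- render_scene(ps$scene, ps$camera, render_params(skip = FALSE))
  expect_identical(on$color, off$color)
  expect_identical(on$depth, off$depth)
  # and with a hidden segment (conservative flag must not create false skips)
  sc <- ps$scene
  sc$nodes[[1]]$tf <- set_segment_opacity(sc$nodes[[1]]$tf, 1L, 0)
  on2 <- render_scene(sc, ps$camera, render_params(skip = TRUE, block_size = 4))
  off2 <- render_scene(sc, ps$camera, render_params(skip = FALSE))
  expect_identical(on2$color, off2$color)
})

test_that("skip grids mark all-transparent blocks and only blocks seeing the bright voxel survive", {
  dims <- c(16L, 16L, 16L)
  data <- array(0, dims)
  data[9, 9, 9] <- 700
  node <- volume_node(scalar_volume(data), tf_opaque())
  node <- build_skip_grid(node, block_size = 4L)
  sg <- node$skip_grid
  expect_equal(sg$nblocks, c(4L, 4L, 4L))
  bright <- sg$max >= 300
  # voxel (8,8,8) 0-based sits in block (2,2,2) 0-based; dilation by one
  # voxel reaches the adjacent blocks (1,.) but no further
  expect_true(bright[3, 3, 3])
  expect_true(bright[2, 3, 3])   # dilated reach
  expect_false(any(bright[c(1, 4), , ]))
  # all-zero volume: every block transparent under a TF transparent at 0
  node0 <- build_skip_grid(volume_node(flat_volume(0), tf_opaque()), 4L)
  expect_true(all(node0$skip_grid$max < 300))
})

test_that("gradient shading follows the Lambert geometry and its degenerate cases", {
  # intensity ramp along +x: gradient +x, normal -x
  g <- expand.grid(i = 0:15, j = 0:15, k = 0:15)
  v <- scalar_volume(array(g$i * 100, c(16, 16, 16)))
  node <- volume_node(v, tf_opaque())
  light_at <- function(pos) point_light(pos, ambient = 0.3, diffuse = 0.7)
  base <- c(1, 0.5, 0.25)
  # light along -x from the sample: normal (-1,0,0) faces it head on
  expect_equal(shade(node, c(8, 8, 8), base, light_at(c(-100, 8, 8))),
               base * (0.3 + 0.7), tolerance = 1e-9)
  # light perpendicular to the normal
  expect_equal(shade(node, c(8, 8, 8), base, light_at(c(8, 300, 8))),
               base * 0.3, tolerance = 1e-6)
  # constant region: zero gradient -> fully lit fallback
  vflat <- volume_node(flat_volume(700), tf_opaque())
  expect_equal(shade(vflat, c(8, 8, 8), base, light_at(c(0, 100, 0))),
               base * (0.3 + 0.7))
})
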