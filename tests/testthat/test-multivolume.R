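test_that("screen rects are symmetric for centered volumes and contain every voxel projection", {
  v <- flat_volume(700)
  node <- volume_node(v, tf_opaque(), pose = pose_translation(c(-7.5, -7.5, -7.5)))
  cam <- camera_look_at(c(0, -80, 0), c(0, 0, 0), up = c(0, 0, 1),
                        image_size = c(101, 101), vfov = 40, near = 1, far = 300)
  r <- project_screen_rect(cam, node)
  # cube centered on the optical axis: covered pixels x0 .. x1-1 are
  # symmetric about the center pixel 50, i.e. x0 + x1 = 101
  expect_equal(unname(r["x0"] + r["x1"]), 101L)
  expect_equal(unname(r["y0"] + r["y1"]), 101L)

  # random-pose volume: every voxel center projects inside the rect
  set.seed(9)
  for (trial in 1:5) {
    pose <- pose_compose(pose_translation(c(runif(2, -15, 15), runif(1, -10, 10))),
                         pose_rotation("z", runif(1, 0, 360)),
                         pose_rotation("y", runif(1, 0, 360)),
                         pose_translation(c(-7.5, -7.5, -7.5)))
    nd <- volume_node(flat_volume(700), tf_opaque(), pose = pose)
    rc <- project_screen_rect(cam, nd)
    g <- as.matrix(expand.grid(0:15, 0:15, 0:15))
    w <- t(pose$matrix %*% rbind(t(g), 1))[, 1:3]
    rel <- sweep(w, 2, cam$eye)
    cz <- rel %*% cam$forward
    expect_true(all(cz > 0))
    tanv <- tan(cam$vfov / 2 * pi / 180)
    px <- ((rel %*% cam$right) / (cz * tanv) + 1) / 2 * 101 - 0.5
    py <- (1 - (rel %*% cam$up) / (cz * tanv)) / 2 * 101 - 0.5
    expect_true(all(px >= rc["x0"] - 0.5 & px <= rc["x1"] - 0.5))
    expect_true(all(py >= rc["y0"] - 0.5 & py <= rc["y1"] - 0.5))
  }
})

test_that("volumes behind the camera give an empty rect; near-plane crossers the full viewport", {
  cam <- camera_look_at(c(0, -80, 0), c(0, 0, 0), up = c(0, 0, 1),
                        image_size = c(64, 64), vfov = 40, near = 1, far = 300)
  behind <- volume_node(flat_volume(700), tf_opaque(),
                        pose = pose_translation(c(-8, -200, -8)))
  r <- project_screen_rect(cam, behind)
  expect_true(r["x1"] <= r["x0"] || r["y1"] <= r["y0"])
  crossing <- volume_node(flat_volume(700), tf_opaque(),
                          pose = pose_translation(c(-8, -85, -8)))
  expect_equal(unname(project_screen_rect(cam, crossing)), c(0L, 64L, 0L, 64L))
})

test_that("depth blits apply a strict less-than test and ties keep the earlier pass", {
  cam <- test_camera(image_size = c(8, 8))
  fb <- make_framebuffer(cam)
  expect_true(all(fb$depth == cam$far))
  pass <- matrix(cam$far, 8, 8)
  fb2 <- blit_depth(fb, pass)
  expect_identical(fb2$depth, fb$depth)           # far everywhere: no-op
  pass[3, 4] <- cam$near
  fb3 <- blit_depth(fb, pass)
  expect_equal(fb3$depth[3, 4], cam$near)
  expect_equal(sum(fb3$depth != cam$far), 1L)     # that pixel only
  fb$depth[5, 5] <- 42
  pass2 <- matrix(cam$far, 8, 8); pass2[5, 5] <- 42
  expect_equal(blit_depth(fb, pass2)$depth[5, 5], 42)  # tie: value retained
  expect_error(blit_depth(fb, matrix(0, 4, 4)), "dims")
})

test_that("a pass against an all-near depth buffer changes nothing", {
  s <- random_blob_scene(1, seed = 2, image_size = c(32, 32))
  cam <- s$camera
  fb <- make_framebuffer(cam)
  fb$depth[] <- cam$near
  res <- render_volume_pass(fb, s$scene$nodes[[1]], cam,
                            render_params(step = 0.5))
  expect_identical(res$fb$color, fb$color)
  expect_true(all(res$pass_depth == cam$far))
})

test_that("a single-node pass reproduces march_single pixel for pixel", {
  s <- random_blob_scene(1, seed = 4, image_size = c(24, 24))
  cam <- s$camera
  node <- s$scene$nodes[[1]]
  params <- render_params(step = 0.5, skip = FALSE)
  r <- render_scene(s$scene, cam, params)
  for (px in list(c(5, 12), c(12, 12), c(18, 7), c(0, 0))) {
    ray <- generate_ray(cam, px)
    m <- march_single(ray, node, params)
    got_rgb <- r$color[px[2] + 1, px[1] + 1, ]
    want_rgb <- m$rgba[1:3]  # over black background
    expect_identical(got_rgb, want_rgb)
    want_depth <- if (is.null(m$hit)) cam$far else m$hit
    expect_identical(r$depth[px[2] + 1, px[1] + 1], want_depth)
  }
})

test_that("pixels outside the screen rect are untouched by a pass", {
  s <- random_blob_scene(1, seed = 6, image_size = c(48, 48))
  cam <- s$camera
  node <- s$scene$nodes[[1]]
  fb <- make_framebuffer(cam, s$scene)
  fb$color[] <- 0.123  # sentinel
  rect <- project_screen_rect(cam, node)
  res <- render_volume_pass(fb, node, cam, render_params(step = 0.5), rect)
  outside <- matrix(TRUE, 48, 48)
  outside[(rect["y0"] + 1):rect["y1"], (rect["x0"] + 1):rect["x1"]] <- FALSE
  for (ch in 1:4)
    expect_true(all(res$fb$color[, , ch][outside] == 0.123))
})

test_that("the final depth buffer is the per-pixel minimum over all pass depths", {
  for (seed in c(1, 3)) {
    s <- random_blob_scene(4, seed = seed, image_size = c(64, 64))
    r <- render_scene(s$scene, s$camera, render_params(),
                      keep_pass_depths = TRUE)
    mind <- Reduce(pmin, r$pass_depths,
                   matrix(s$camera$far, 64, 64))
    expect_identical(r$depth, mind)
  }
})

test_that("an empty scene renders background color and far depth", {
  cam <- test_camera(image_size = c(16, 16))
  sc <- scene(background = c(0.1, 0.2, 0.3))
  r <- render_scene(sc, cam)
  expect_true(all(r$depth == cam$far))
  expect_equal(as.vector(r$color[4, 9, ]), c(0.1, 0.2, 0.3))
  expect_true(all(r$alpha == 0))
})

test_that("naive blending without depth testing breaks occlusion; the depth buffer repairs it", {
  s <- overlapping_bars_scene(seed = 0, image_size = c(96, 96))
  params <- render_params(align_global_grid = TRUE)
  oracle <- render_onepass(s$scene, s$camera, params)
  naive <- render_scene(s$scene, s$camera, params, depth_test = FALSE)
  correct <- render_scene(s$scene, s$camera, params)
  expect_gt(sum(diff_pixel_mask(naive, oracle)), 0)
  expect_equal(sum(diff_pixel_mask(correct, oracle)), 0)
})

test_that("an opaque layer in front occludes volumes and its depth converts per pixel", {
  s <- random_blob_scene(1, seed = 8, image_size = c(32, 32))
  cam <- s$camera
  plain <- render_scene(s$scene, cam, render_params())
  expect_gt(mean(plain$alpha > 0), 0)
  # opaque plane 5 mm in front of the eye, covering everything
  layer_col <- array(rep(c(0.5, 0.6, 0.7), each = 32 * 32), c(32, 32, 3))
  layer_depth <- matrix(5, 32, 32)  # camera-space z
  sc <- s$scene
  sc$opaque_layer <- list(color = layer_col, depth = layer_depth)
  r <- render_scene(sc, cam, render_params())
  expect_true(all(r$alpha == 0))
  expect_equal(as.vector(r$color[7, 9, ]), c(0.5, 0.6, 0.7))
  # ray distance to a z=5 plane grows away from the image center
  expect_gt(r$depth[1, 1], r$depth[16, 16])
  expect_equal(min(r$depth), 5, tolerance = 1e-3)
})

test_that("front-to-back node ordering leaves the rendered image unchanged", {
  s <- random_blob_scene(4, seed = 12, image_size = c(48, 48))
  a <- render_scene(s$scene, s$camera, render_params(align_global_grid = TRUE))
  b <- render_scene(s$scene, s$camera, render_params(align_global_grid = TRUE),
                    order = "front-to-back")
  expect_identical(a$color, b$color)
  expect_identical(a$depth, b$depth)
})

test_that("shadow maps record first-hit distances from the light and darken occluded points", {
  # slab between the light and a wall
  wall <- volume_node(flat_volume(700, dims = c(32L, 32L, 4L)),
                      tf_opaque(), pose = pose_translation(c(-15.5, -15.5, -20)))
  slab <- volume_node(flat_volume(700, dims = c(12L, 12L, 4L)),
                      tf_opaque(), pose = pose_translation(c(-5.5, -5.5, 8)))
  light <- point_light(c(0, 0, 60), shadow_map_size = 128L)
  sc <- scene(wall, slab, light = light)
  sm <- render_shadow_map(sc, params = render_params(step = 0.5, skip = FALSE))
  # texel toward the slab: first hit on the slab's top face (z = 11.5)
  # vs a clear texel toward the wall only
  behind <- c(0, 0, -16)   # wall point shadowed by the slab
  open <- c(13, 13, -16)   # wall point with a clear line to the light
  d_behind <- sqrt(sum((behind - light$position)^2))
  d_open <- sqrt(sum((open - light$position)^2))
  occ_behind <- voxray:::shadow_lookup(sm, behind)
  occ_open <- voxray:::shadow_lookup(sm, open)
  expect_lt(occ_behind + sm$bias, d_behind)   # occluded
  expect_gte(occ_open + sm$bias, d_open)      # lit
  # per-texel oracle: center texel distance equals light-to-slab-surface
  ctr_t <- sm$depth[64, 64]
  expect_equal(ctr_t, 60 - 11.5, tolerance = sm$bias + 1e-9)
  # no volumes: every texel far, everything lit
  sm0 <- render_shadow_map(scene(light = light))
  expect_true(all(sm0$depth >= 1e9))
  expect_equal(voxray:::shadow_lookup(sm0, behind), 1e9)
})
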