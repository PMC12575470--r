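# Shared fixture builders. All fixtures are generated in code; none are
# stored on disk.

# Volume whose voxel value encodes its own coordinates, handy for
# checking interpolation exactly: v(i,j,k) = i + 10 j + 100 k.
coord_volume <- function(dims = c(5L, 5L, 5L), spacing = c(1, 1, 1)) {
  g <- expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                   k = 0:(dims[3] - 1L))
  scalar_volume(array(g$i + 10 * g$j + 100 * g$k, dims), spacing = spacing)
}

# Homogeneous volume of a single intensity.
flat_volume <- function(value, dims = c(16L, 16L, 16L), spacing = c(1, 1, 1)) {
  scalar_volume(array(value, dims), spacing = spacing)
}

# Fully opaque step TF and a constant semi-transparent TF.
tf_opaque <- function(color = c(1, 0, 0), threshold = 300)
  tf_preset("bone_binary", threshold = threshold, color = color)

tf_constant_alpha <- function(alpha, color = c(0, 1, 0), reference_step = 1)
  transfer_function(c(-1e4, 1e4),
                    rbind(c(color, alpha), c(color, alpha)),
                    reference_step = reference_step)

# A camera 60 mm up the +x axis looking back at the origin.
test_camera <- function(image_size = c(64, 64), eye = c(60, 0, 0),
                        vfov = 45, far = 400)
  camera_look_at(eye, c(0, 0, 0), up = c(0, 0, 1), vfov = vfov,
                 image_size = image_size, near = 1, far = far)

# Independent 8-corner trilinear oracle (explicit weight sum with
# boundary clamping), kept separate from the renderer's sampling code.
trilinear_oracle <- function(data, p) {
  d <- dim(data)
  p <- pmin(pmax(p, 0), d - 1)
  i0 <- pmin(floor(p), d - 2); i0 <- pmax(i0, 0)
  f <- p - i0
  val <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    idx <- pmin(i0 + c(cx, cy, cz), d - 1) + 1
    w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
    val <- val + w * data[idx[1], idx[2], idx[3]]
  }
  val
}

# 6-connectivity of a logical 3D array: iterative dilation from one seed
# voxel restricted to the set, until a fixed point.
is_connected6 <- function(set) {
  if (!any(set)) return(TRUE)
  d <- dim(set)
  reached <- array(FALSE, d)
  seed <- which(set)[1]
  reached[seed] <- TRUE
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- list(1:d[1], 1:d[2], 1:d[3])
    n <- d[ax]
    if (by == 1) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  repeat {
    grown <- reached
    for (ax in 1:3) for (by in c(1, -1))
      grown <- grown | shift(reached, ax, by)
    grown <- grown & set
    if (identical(grown, reached)) break
    reached <- grown
  }
  all(reached[set])
}

# Pixels differing in any channel between two renders.
diff_pixel_mask <- function(a, b)
  apply(abs(a$color - b$color), c(1, 2), max) > 0

# Dilate a logical pixel mask by one pixel (Chebyshev).
dilate1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    ys <- pmin(pmax(1:H + dy, 1), H)
    xs <- pmin(pmax(1:W + dx, 1), W)
    out <- out | m[ys, xs]
  }
  out
}
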