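#' Rendering parameters
#'
#' @param step sampling interval in mm. `NULL` (default) picks
#'   `0.5 * min(voxel spacing)` over the scene at render time.
#' @param alpha_threshold early-ray-termination opacity in `(0, 1]`;
#'   once a ray's accumulated opacity reaches it, the hit distance is
#'   recorded and marching stops. Default 0.99.
#' @param align_global_grid sample at global multiples `t = k * step`
#'   of the distance from the eye instead of at per-volume segment
#'   midpoints `t_enter + (k + 1/2) * step`. The global grid makes every
#'   pass (and the one-pass reference renderer) take samples at exactly
#'   the same distances, at the cost of a half-step boundary bias.
#' @param shading enable gradient (Lambert) shading; requires a scene
#'   light.
#' @param skip enable min-max empty-space skipping.
#' @param block_size skip-grid block edge length in voxels (>= 2).
#' @return An object of class `voxray_params`.
#' @export
render_params <- function(step = NULL, alpha_threshold = 0.99,
                          align_global_grid = FALSE, shading = FALSE,
                          skip = TRUE, block_size = 8L) {
  if (!is.null(step) && step <= 0) stop("step must be > 0")
  if (alpha_threshold <= 0 || alpha_threshold > 1)
    stop("alpha_threshold must be in (0, 1]")
  if (block_size < 2L) stop("block_size must be >= 2")
  structure(
    list(step = step, alpha_threshold = alpha_threshold,
         align_global_grid = isTRUE(align_global_grid),
         shading = isTRUE(shading), skip = isTRUE(skip),
         block_size = as.integer(block_size)),
    class = "voxray_params")
}

resolve_step <- function(params, sc) {
  if (!is.null(params$step)) return(params$step)
  0.5 * min(vapply(sc$nodes, function(n) min(n$volume$spacing), 0))
}

#' Ray / axis-aligned box intersection
#'
#' Slab-method intersection of a ray with an axis-aligned box, the ray
#' already expressed in the box's frame. The entry distance is clamped
#' to the ray's `t_near` (a ray starting inside the box enters at
#' `t_near`), and the interval is intersected with
#' `[t_near, t_far]`.
#'
#' @param ray a `voxray_ray` (see [generate_ray()]), in the box frame.
#' @param lo,hi box corner coordinates.
#' @return `c(t_enter, t_exit)`, or `NULL` on a miss.
#' @export
intersect_ray_aabb <- function(ray, lo, hi) {
  tE <- ray$t_near
  tX <- ray$t_far
  for (a in 1:3) {
    d <- ray$direction[a]
    o <- ray$origin[a]
    if (d != 0) {
      ta <- (lo[a] - o) / d
      tb <- (hi[a] - o) / d
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      tE <- max(tE, ta)
      tX <- min(tX, tb)
    } else if (o < lo[a] || o > hi[a]) {
      return(NULL)
    }
  }
  if (tE >= tX) return(NULL)
  c(t_enter = tE, t_exit = tX)
}

# Flat list representation of a node handed to the C++ kernels.
# `step` is needed to bake the skip grid's per-block transparency
# decision; `light` carries the shading setup (or NULL).
node_internal <- function(node, params, step, light = NULL) {
  inv <- solve(node$pose$matrix)
  lin <- node$pose$matrix[1:3, 1:3]
  box <- node_local_box(node)
  skip <- NULL
  if (isTRUE(params$skip) && !is.null(node$skip_grid)) {
    sg <- node$skip_grid
    segop <- node$tf$segment_opacity
    nb <- prod(sg$nblocks)
    transparent <- vapply(seq_len(nb), function(i)
      tf_max_alpha(node$tf, sg$min[i], sg$max[i]) == 0, TRUE)
    any_hidden <- any(segop < 1)
    skippable <- transparent & !(as.vector(sg$has_label) & any_hidden)
    skip <- list(block_size = sg$block_size, nblocks = sg$nblocks,
                 skippable = as.integer(skippable))
  }
  list(
    data = node$volume$data,
    dims = as.integer(node$volume$dims),
    spacing = node$volume$spacing,
    inv = inv,
    nrm = t(solve(lin)),
    mask = if (is.null(node$mask)) NULL else node$mask$labels,
    tf_x = node$tf$intensities,
    tf_rgba = node$tf$colors,
    tf_interp = if (node$tf$interpolation == "constant") 1L else 0L,
    segop = node$tf$segment_opacity,
    reference_step = node$tf$reference_step,
    box_lo = box$lo,
    box_hi = box$hi,
    skip = skip)
}

params_internal <- function(params, step, light = NULL) {
  li <- NULL
  if (params$shading && !is.null(light)) {
    sh <- NULL
    if (!is.null(light$shadow)) {
      sh <- list(depth = light$shadow$depth,
                 camera = camera_internal(light$shadow$camera),
                 bias = light$shadow$bias)
    }
    li <- list(position = light$position, ambient = light$ambient,
               diffuse = light$diffuse, shadow = sh)
  }
  list(step = step, alpha_threshold = params$alpha_threshold,
       align_global_grid = params$align_global_grid,
       shading = params$shading && !is.null(light),
       light = li)
}

#' March a single ray through one volume node
#'
#' Front-to-back compositing `C <- C + (1 - A) * alpha * c`,
#' `A <- A + (1 - A) * alpha` over samples inside
#' `[t_enter, min(t_exit, t_clamp))`, where `t_enter`/`t_exit` come from
#' the ray/box intersection. The hit distance is the sample distance at
#' which `A` first reaches the early-termination threshold, or `NULL`.
#'
#' @param ray a `voxray_ray` in world space.
#' @param node a [volume_node()].
#' @param params a [render_params()] (its `step` must be set).
#' @param t_clamp occlusion clamp distance along the ray (mm); samples
#'   at or beyond it are not taken. Defaults to the ray's `t_far`.
#' @param light optional [point_light()] for shading.
#' @return List with `rgba` (premultiplied color + accumulated opacity)
#'   and `hit` (distance in mm, or `NULL`).
#' @export
march_single <- function(ray, node, params = render_params(step = NULL),
                         t_clamp = ray$t_far, light = NULL) {
  step <- params$step
  if (is.null(step)) step <- 0.5 * min(node$volume$spacing)
  if (t_clamp > ray$t_far) stop("t_clamp must be <= the ray's t_far")
  ni <- node_internal(node, params, step)
  pr <- params_internal(params, step, light)
  out <- cpp_march_ray(ni, pr, ray$origin, ray$direction,
                       ray$t_near, min(ray$t_far, t_clamp))
  list(rgba = out$rgba, hit = if (out$hit >= 0) out$hit else NULL)
}

#' Build an empty-space-skipping grid for a node
#'
#' Partitions the volume into cubic blocks and records each block's
#' intensity min/max over the block dilated by one voxel (so the
#' trilinear support of any sample inside the block is covered) plus a
#' flag marking blocks that touch any labeled voxel. At render time a
#' block is skipped only if the transfer function is provably zero over
#' its whole intensity range and the block contains no voxel of a
#' hidden segment; skipping therefore never changes the rendered image.
#'
#' @param node a [volume_node()].
#' @param block_size block edge length in voxels (>= 2).
#' @return The node with its `skip_grid` field populated.
#' @export
build_skip_grid <- function(node, block_size = 8L) {
  block_size <- as.integer(block_size)
  if (block_size < 2L) stop("block_size must be >= 2")
  bm <- cpp_block_minmax(as.double(node$volume$data),
                         as.integer(node$volume$dims),
                         if (is.null(node$mask)) NULL else node$mask$labels,
                         block_size)
  node$skip_grid <- list(block_size = block_size, nblocks = bm$nblocks,
                         min = bm$min, max = bm$max,
                         has_label = bm$has_label)
  node
}

#' Gradient shading of a sample
#'
#' Lambert shading used by the renderer when `shading = TRUE`: the
#' surface normal is the negated, normalised central-difference
#' intensity gradient (transformed to world space), and the output is
#' `base * (ambient + diffuse * max(0, n . l) * visibility)`. Regions of
#' constant intensity have no surface and are treated as fully lit
#' (diffuse factor 1). Visibility is 1 unless a shadow map reports the
#' point occluded.
#'
#' @param node a [volume_node()].
#' @param p sample position in continuous 0-based voxel coordinates.
#' @param base RGB color before shading.
#' @param light a [point_light()].
#' @param shadow optional shadow map from [render_shadow_map()].
#' @return Shaded RGB.
#' @export
shade <- function(node, p, base, light, shadow = NULL) {
  sp <- node$volume$spacing
  v <- node$volume
  g <- c(
    (sample_intensity(v, p + c(1, 0, 0)) - sample_intensity(v, p - c(1, 0, 0))) / (2 * sp[1]),
    (sample_intensity(v, p + c(0, 1, 0)) - sample_intensity(v, p - c(0, 1, 0))) / (2 * sp[2]),
    (sample_intensity(v, p + c(0, 0, 1)) - sample_intensity(v, p - c(0, 0, 1))) / (2 * sp[3]))
  nrm_mat <- t(solve(node$pose$matrix[1:3, 1:3]))
  gw <- as.numeric(nrm_mat %*% g)
  pw <- transform_point(node$pose, p * sp)
  vis <- 1
  if (!is.null(shadow)) {
    dist <- sqrt(sum((pw - light$position)^2))
    occ <- shadow_lookup(shadow, pw)
    vis <- as.numeric(dist <= occ + shadow$bias)
  }
  gl <- sqrt(sum(gw^2))
  if (gl < 1e-12) {
    diff <- 1
  } else {
    l <- light$position - pw
    ll <- sqrt(sum(l^2))
    diff <- if (ll < 1e-12) 1 else max(0, -sum(gw * l) / (gl * ll))
  }
  base * (light$ambient + light$diffuse * diff * vis)
}

# Distance-to-light stored in the shadow map at the texel covering
# world point pw (far / +Inf semantics: lit when outside the map).
shadow_lookup <- function(shadow, pw) {
  cam <- shadow$camera
  r <- pw - cam$eye
  cz <- sum(r * cam$forward)
  if (cz <= cam$near) return(Inf)
  tanv <- tan(cam$vfov / 2 * pi / 180)
  aspect <- cam$image_size[1] / cam$image_size[2]
  px <- (sum(r * cam$right) / (cz * tanv * aspect) + 1) / 2 * cam$image_size[1] - 0.5
  py <- (1 - sum(r * cam$up) / (cz * tanv)) / 2 * cam$image_size[2] - 0.5
  ix <- round(px); iy <- round(py)
  if (ix < 0 || iy < 0 || ix >= cam$image_size[1] || iy >= cam$image_size[2])
    return(Inf)
  shadow$depth[iy + 1L, ix + 1L]
}
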