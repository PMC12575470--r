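#' Create an empty frame buffer
#'
#' Color is held premultiplied (RGB already scaled by opacity, plus an
#' accumulated-opacity channel) and resolved over the background only at
#' the end; depth holds per-pixel hit distances along the ray (mm),
#' initialised to the far plane. If the scene carries an opaque layer
#' (pre-rendered meshes: color + camera-space depth), the buffer starts
#' from that layer, with its depths converted to ray distances.
#'
#' @param cam a [camera()].
#' @param sc optional [scene()] providing background / opaque layer.
#' @return A `voxray_framebuffer`: list with `color` (H x W x 4
#'   premultiplied RGBA), `depth` (H x W), `background` (H x W x 3).
#' @export
make_framebuffer <- function(cam, sc = NULL) {
  W <- cam$image_size[1]; H <- cam$image_size[2]
  color <- array(0, c(H, W, 4))
  depth <- matrix(cam$far, H, W)
  bgc <- if (is.null(sc)) c(0, 0, 0) else sc$background
  background <- array(rep(bgc, each = H * W), c(H, W, 3))
  if (!is.null(sc) && !is.null(sc$opaque_layer)) {
    ol <- sc$opaque_layer
    if (!identical(dim(ol$depth), c(H, W)))
      stop("opaque layer depth dims do not match the camera image size")
    if (!identical(dim(ol$color)[1:2], c(H, W)))
      stop("opaque layer color dims do not match the camera image size")
    # camera-space z -> distance along each pixel's ray
    t_layer <- ol$depth * ray_distance_factors(cam)
    depth <- pmin(t_layer, cam$far)
    background <- ol$color
  }
  structure(list(color = color, depth = depth, background = background),
            class = "voxray_framebuffer")
}

#' @export
print.voxray_framebuffer <- function(x, ...) {
  d <- dim(x$color)
  cat(sprintf("<voxray_framebuffer> %d x %d px, depth range [%.4g, %.4g] mm\n",
              d[2], d[1], min(x$depth), max(x$depth)))
  invisible(x)
}

#' Resolve a frame buffer to an RGB image
#'
#' Composites the accumulated premultiplied color over the background
#' (or opaque layer): `rgb = C + (1 - A) * background`.
#'
#' @param fb a `voxray_framebuffer`.
#' @return H x W x 3 linear RGB array.
#' @export
resolve_framebuffer <- function(fb) {
  A <- fb$color[, , 4]
  out <- fb$color[, , 1:3, drop = FALSE] + as.vector(1 - A) * fb$background
  dimnames(out) <- NULL
  out
}

#' Screen-space bounding rectangle of a volume node
#'
#' Projects the eight world-space corners of the node's local box into
#' the camera's screen space and returns the pixel bounding rectangle,
#' padded by one pixel and clipped to the viewport. A box entirely at or
#' behind the near plane gives an empty rectangle (the pass is skipped);
#' if only some corners are at or behind it the full viewport is
#' returned (safe over-approximation); a box projecting entirely outside
#' the viewport also gives an empty rectangle.
#'
#' @param cam a [camera()].
#' @param node a [volume_node()].
#' @return A `voxray_rect`: integer `c(x0, x1, y0, y1)`, half-open
#'   0-based pixel bounds (`x0 <= x < x1`).
#' @export
project_screen_rect <- function(cam, node) {
  W <- cam$image_size[1]; H <- cam$image_size[2]
  full <- screen_rect(0L, W, 0L, H)
  cs <- node_world_corners(node)
  rel <- sweep(cs, 2, cam$eye)
  cz <- rel %*% cam$forward
  if (all(cz <= cam$near)) return(screen_rect(0L, 0L, 0L, 0L))
  if (any(cz <= cam$near)) return(full)
  tanv <- tan(cam$vfov / 2 * pi / 180)
  aspect <- W / H
  px <- ((rel %*% cam$right) / (cz * tanv * aspect) + 1) / 2 * W - 0.5
  py <- (1 - (rel %*% cam$up) / (cz * tanv)) / 2 * H - 0.5
  x0 <- max(0L, as.integer(floor(min(px))) - 1L)
  x1 <- min(W, as.integer(ceiling(max(px))) + 2L)
  y0 <- max(0L, as.integer(floor(min(py))) - 1L)
  y1 <- min(H, as.integer(ceiling(max(py))) + 2L)
  if (x1 <= x0 || y1 <= y0) return(screen_rect(0L, 0L, 0L, 0L))
  screen_rect(x0, x1, y0, y1)
}

screen_rect <- function(x0, x1, y0, y1) {
  structure(c(x0 = as.integer(x0), x1 = as.integer(x1),
              y0 = as.integer(y0), y1 = as.integer(y1)),
            class = "voxray_rect")
}

rect_is_empty <- function(r) r["x1"] <= r["x0"] || r["y1"] <= r["y0"]

#' Blit a pass depth image into the frame buffer with depth testing
#'
#' Per pixel inside `rect`, the frame-buffer depth is replaced by the
#' pass depth only where the pass depth is strictly smaller; ties keep
#' the value written by the earlier pass.
#'
#' @param fb a `voxray_framebuffer`.
#' @param pass_depth H x W pass hit-distance image (far where no hit).
#' @param rect a rectangle from [project_screen_rect()]; defaults to the
#'   full image.
#' @return The updated frame buffer.
#' @export
blit_depth <- function(fb, pass_depth, rect = NULL) {
  if (!identical(dim(pass_depth), dim(fb$depth)))
    stop("pass_depth dims do not match the frame buffer")
  if (is.null(rect)) {
    H <- dim(fb$depth)[1]; W <- dim(fb$depth)[2]
    rect <- screen_rect(0L, W, 0L, H)
  }
  if (rect_is_empty(rect)) return(fb)
  ys <- (rect["y0"] + 1L):rect["y1"]
  xs <- (rect["x0"] + 1L):rect["x1"]
  old <- fb$depth[ys, xs, drop = FALSE]
  new <- pass_depth[ys, xs, drop = FALSE]
  fb$depth[ys, xs] <- ifelse(new < old, new, old)
  fb
}

#' Render one volume pass into a frame buffer
#'
#' Marches every pixel inside the node's screen rectangle, clamping each
#' ray at the frame buffer's current depth (occlusion by earlier passes
#' or the opaque layer), composites the pass output over the existing
#' color (`C <- C_pass + (1 - A_pass) * C`), and returns the per-pixel
#' hit-distance image of the pass alongside the updated buffer. The
#' caller is responsible for blitting the pass depth
#' (see [blit_depth()]); [render_scene()] drives both.
#'
#' @param fb a `voxray_framebuffer`.
#' @param node a visible [volume_node()].
#' @param cam a [camera()].
#' @param params a [render_params()] with `step` resolved.
#' @param rect rectangle of pixels to process (defaults to
#'   [project_screen_rect()]).
#' @param light optional [point_light()] for shading.
#' @param verbose print a one-line pass log.
#' @return List with `fb` (updated buffer) and `pass_depth`.
#' @export
render_volume_pass <- function(fb, node, cam, params, rect = NULL,
                               light = NULL, verbose = FALSE) {
  if (is.null(rect)) rect <- project_screen_rect(cam, node)
  H <- dim(fb$depth)[1]; W <- dim(fb$depth)[2]
  if (rect_is_empty(rect)) {
    if (verbose)
      message(sprintf("pass '%s': empty screen rect, skipped", node$name))
    return(list(fb = fb, pass_depth = matrix(cam$far, H, W)))
  }
  step <- params$step
  if (is.null(step)) step <- 0.5 * min(node$volume$spacing)
  if (isTRUE(params$skip) && is.null(node$skip_grid))
    node <- build_skip_grid(node, params$block_size)
  ni <- node_internal(node, params, step)
  pr <- params_internal(params, step, light)
  out <- cpp_render_pass(ni, camera_internal(cam), pr,
                         as.integer(rect), fb$depth, FALSE)
  if (verbose)
    message(sprintf(
      "pass '%s': rect [%d,%d)x[%d,%d), %d pixels marched, %.1f%% early-terminated",
      node$name, rect["x0"], rect["x1"], rect["y0"], rect["y1"],
      as.integer(out$pixels), 100 * out$hits / max(1, out$pixels)))
  # composite the pass over the existing color (premultiplied "over")
  Ap <- out$color[, , 4]
  fb$color <- out$color + as.vector(1 - Ap) * fb$color
  list(fb = fb, pass_depth = out$depth)
}

#' Render a scene with consecutive depth-clamped volume passes
#'
#' The multi-pass, depth-buffer-based multi-volume renderer: the frame
#' buffer starts from the background (or the pre-rendered opaque
#' layer), then every visible node is rendered in creation order (or
#' sorted front to back), each pass clamping its rays at the current
#' per-pixel depth and blitting its own hit distances back with depth
#' testing. Correct occlusion between intersecting volumes therefore
#' emerges from the shared depth buffer, provided transfer functions do
#' not produce many semi-transparent voxels; a scene of mostly opaque
#' classifications reproduces the one-pass reference renderer exactly.
#'
#' @param sc a [scene()].
#' @param cam a [camera()].
#' @param params a [render_params()].
#' @param order `"creation"` (default) or `"front-to-back"`
#'   (nodes sorted by distance from the eye to the box center, an
#'   optional performance heuristic).
#' @param use_rect use per-volume screen rectangles (disable to force
#'   full-viewport passes; the image is unchanged).
#' @param depth_test use the shared depth buffer (clamping + blit).
#'   Disabling reproduces naive independent-pass alpha blending, which
#'   renders intersecting volumes incorrectly; for comparison only.
#' @param keep_pass_depths return each pass's depth image.
#' @param verbose print one line per pass.
#' @return A `voxray_render`: list with `color` (H x W x 3 resolved
#'   linear RGB), `alpha` (H x W accumulated opacity), `depth`
#'   (H x W ray-distance buffer) and optionally `pass_depths`.
#' @export
render_scene <- function(sc, cam, params = render_params(),
                         order = c("creation", "front-to-back"),
                         use_rect = TRUE, depth_test = TRUE,
                         keep_pass_depths = FALSE, verbose = FALSE) {
  order <- match.arg(order)
  fb <- make_framebuffer(cam, sc)
  nodes <- Filter(function(n) n$visible, sc$nodes)
  params$step <- if (length(nodes)) resolve_step(params, sc) else 1
  if (order == "front-to-back" && length(nodes) > 1L) {
    d <- vapply(nodes, function(n) {
      b <- node_local_box(n)
      ctr <- transform_point(n$pose, (b$lo + b$hi) / 2)
      sqrt(sum((ctr - cam$eye)^2))
    }, 0)
    nodes <- nodes[order(d)]
  }
  H <- cam$image_size[2]; W <- cam$image_size[1]
  pass_depths <- list()
  for (node in nodes) {
    rect <- if (use_rect) project_screen_rect(cam, node)
            else screen_rect(0L, W, 0L, H)
    if (!depth_test) {
      # naive variant: no clamping, no depth blit
      clamp_free <- fb
      clamp_free$depth <- matrix(cam$far, H, W)
      res <- render_volume_pass(clamp_free, node, cam, params, rect,
                                light = sc$light, verbose = verbose)
      res$fb$depth <- fb$depth
      fb <- res$fb
    } else {
      res <- render_volume_pass(fb, node, cam, params, rect,
                                light = sc$light, verbose = verbose)
      fb <- blit_depth(res$fb, res$pass_depth, rect)
    }
    if (keep_pass_depths)
      pass_depths[[node$name]] <- res$pass_depth
  }
  out <- list(color = resolve_framebuffer(fb),
              alpha = fb$color[, , 4],
              depth = fb$depth,
              camera = cam, params = params)
  if (keep_pass_depths) out$pass_depths <- pass_depths
  class(out) <- "voxray_render"
  out
}

#' @export
print.voxray_render <- function(x, ...) {
  d <- dim(x$color)
  cat(sprintf("<voxray_render> %d x %d px, %.1f%% covered, depth range [%.4g, %.4g] mm\n",
              d[2], d[1], 100 * mean(x$alpha > 0), min(x$depth), max(x$depth)))
  invisible(x)
}

#' Render a depth-only shadow map from the scene's light
#'
#' Runs the multi-pass machinery from a camera placed at the light,
#' computing only hit distances: per texel the distance from the light
#' to the first point where a ray's accumulated opacity reaches the
#' early-termination threshold, the far distance where none. The light
#' camera is aimed at the scene center with a frustum wide enough to
#' enclose the world bounds of all nodes.
#'
#' @param sc a [scene()] (its `light` is used unless `light` is given).
#' @param light a [point_light()].
#' @param params a [render_params()].
#' @return A `voxray_shadow_map`: list with `depth` (S x S distances to
#'   the light), `camera` (the light-view camera) and `bias` (mm).
#' @export
render_shadow_map <- function(sc, light = sc$light,
                              params = render_params()) {
  if (is.null(light)) stop("scene has no light")
  nodes <- Filter(function(n) n$visible, sc$nodes)
  if (!length(nodes)) {
    # nothing casts shadows: an all-far map leaves every surface lit
    S <- light$shadow_map_size
    lcam <- camera_look_at(light$position, light$position + c(1e-3, 0, -1),
                           up = c(0, 1, 0), vfov = 90,
                           image_size = c(S, S), near = 1e-3, far = 1e9)
    return(structure(list(depth = matrix(1e9, S, S), camera = lcam,
                          bias = 0), class = "voxray_shadow_map"))
  }
  params$step <- resolve_step(params, sc)
  b <- scene_world_bounds(sc)
  ctr <- (b$lo + b$hi) / 2
  radius <- sqrt(sum((b$hi - b$lo)^2)) / 2
  dist <- sqrt(sum((ctr - light$position)^2))
  if (dist <= radius)
    stop("light camera frustum cannot enclose the scene: light inside scene bounds")
  vfov <- 2 * asin(min(1, radius / dist)) * 180 / pi * 1.1
  near <- max(1e-3, dist - radius * 1.1)
  far <- dist + radius * 1.1
  S <- light$shadow_map_size
  lcam <- camera_look_at(light$position, ctr,
                         up = pick_up_vector(ctr - light$position),
                         vfov = min(vfov, 170),
                         image_size = c(S, S), near = near, far = far)
  depth <- matrix(far, S, S)
  fb <- list(depth = depth)
  pr <- params
  pr$shading <- FALSE
  for (node in nodes) {
    if (isTRUE(pr$skip) && is.null(node$skip_grid))
      node <- build_skip_grid(node, pr$block_size)
    ni <- node_internal(node, pr, pr$step)
    pint <- params_internal(pr, pr$step)
    out <- cpp_render_pass(ni, camera_internal(lcam), pint,
                           as.integer(screen_rect(0L, S, 0L, S)),
                           fb$depth, TRUE)
    fb$depth <- ifelse(out$depth < fb$depth, out$depth, fb$depth)
  }
  structure(list(depth = fb$depth, camera = lcam,
                 bias = 2 * pr$step),
            class = "voxray_shadow_map")
}

pick_up_vector <- function(fwd) {
  fwd <- fwd / sqrt(sum(fwd^2))
  if (abs(fwd[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
}

#' Attach a freshly rendered shadow map to the scene light
#'
#' @param sc a [scene()] with a light.
#' @param params a [render_params()].
#' @return The scene, with `sc$light$shadow` populated.
#' @export
update_light_shadow <- function(sc, params = render_params()) {
  sm <- render_shadow_map(sc, params = params)
  sc$light$shadow <- sm
  sc
}
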