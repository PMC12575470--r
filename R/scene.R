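#' Volume node
#'
#' One renderable entry of a scene: a scalar volume, an optional
#' co-registered segmentation mask, a transfer function, a local-to-world
#' pose and a visibility flag. Nodes are rendered in ascending
#' `creation_index` by default (order of creation).
#'
#' @param volume a [scalar_volume()].
#' @param tf a [transfer_function()].
#' @param mask optional [segmentation_mask()] with the volume's dims.
#' @param pose a [affine_pose()] mapping the node's local mm frame to
#'   world mm. If missing and the volume carries a `pose` attribute
#'   (set by [read_volume()]), that is used.
#' @param visible logical; invisible nodes are skipped by the renderer.
#' @param name identifier used in logs.
#' @return An object of class `voxray_node`.
#' @export
volume_node <- function(volume, tf, mask = NULL, pose = NULL,
                        visible = TRUE, name = volume$name) {
  if (!inherits(volume, "voxray_volume")) stop("`volume` must be a scalar_volume")
  if (!inherits(tf, "voxray_tf")) stop("`tf` must be a transfer_function")
  if (!is.null(mask)) {
    if (!inherits(mask, "voxray_mask")) stop("`mask` must be a segmentation_mask")
    stopifnot_mask_matches(mask, volume)
  }
  if (is.null(pose)) {
    pose <- attr(volume, "pose")
    if (is.null(pose)) pose <- affine_pose()
  }
  if (!inherits(pose, "voxray_pose")) stop("`pose` must be an affine_pose")
  structure(
    list(volume = volume, mask = mask, tf = tf, pose = pose,
         visible = isTRUE(visible), creation_index = NA_integer_,
         skip_grid = NULL, name = as.character(name)[1]),
    class = "voxray_node")
}

#' @export
print.voxray_node <- function(x, ...) {
  cat(sprintf("<voxray_node '%s'> %s%s, creation index %s\n",
              x$name, paste(x$volume$dims, collapse = "x"),
              if (is.null(x$mask)) "" else " + mask",
              x$creation_index))
  invisible(x)
}

# Local-mm sampling box of a node: [-0.5, dim - 0.5] * spacing per axis.
node_local_box <- function(node) {
  sp <- node$volume$spacing
  list(lo = -0.5 * sp, hi = (node$volume$dims - 0.5) * sp)
}

# World-space corners (8 x 3) of the node's local box.
node_world_corners <- function(node) {
  b <- node_local_box(node)
  g <- as.matrix(expand.grid(x = c(b$lo[1], b$hi[1]),
                             y = c(b$lo[2], b$hi[2]),
                             z = c(b$lo[3], b$hi[3])))
  t(node$pose$matrix %*% rbind(t(g), 1))[, 1:3, drop = FALSE]
}

#' Scene
#'
#' An ordered list of volume nodes plus a background color, an optional
#' point light and an optional pre-rendered opaque layer (color image +
#' camera-space depth image, e.g. rasterised instrument meshes).
#'
#' @param ... [volume_node()] objects (or a single list of them).
#' @param background RGB background color in `[0, 1]`.
#' @param light optional [point_light()].
#' @param opaque_layer optional list with `color` (H x W x 3 linear RGB)
#'   and `depth` (H x W camera-space z in mm, far-plane value where
#'   empty).
#' @return An object of class `voxray_scene`.
#' @export
scene <- function(..., background = c(0, 0, 0), light = NULL,
                  opaque_layer = NULL) {
  nodes <- list(...)
  if (length(nodes) == 1L && is.list(nodes[[1]]) &&
      !inherits(nodes[[1]], "voxray_node"))
    nodes <- nodes[[1]]
  sc <- structure(
    list(nodes = list(), background = as.numeric(background),
         light = light, opaque_layer = opaque_layer,
         next_index = 1L),
    class = "voxray_scene")
  for (n in nodes) sc <- scene_add_node(sc, n)
  sc
}

#' Append a node to a scene
#'
#' The node receives the next creation index; the default render order
#' is the order of creation.
#'
#' @param sc a [scene()].
#' @param node a [volume_node()].
#' @return The updated scene.
#' @export
scene_add_node <- function(sc, node) {
  if (!inherits(node, "voxray_node")) stop("`node` must be a volume_node")
  node$creation_index <- sc$next_index
  sc$next_index <- sc$next_index + 1L
  sc$nodes[[length(sc$nodes) + 1L]] <- node
  sc
}

#' @export
print.voxray_scene <- function(x, ...) {
  cat(sprintf("<voxray_scene> %d node(s)%s%s\n", length(x$nodes),
              if (is.null(x$light)) "" else ", point light",
              if (is.null(x$opaque_layer)) "" else ", opaque layer"))
  for (n in x$nodes)
    cat(sprintf("  [%d] '%s' %s%s%s\n", n$creation_index, n$name,
                paste(n$volume$dims, collapse = "x"),
                if (is.null(n$mask)) "" else " +mask",
                if (n$visible) "" else " (hidden)"))
  invisible(x)
}

# World-space AABB enclosing all visible node boxes.
scene_world_bounds <- function(sc) {
  cs <- do.call(rbind, lapply(sc$nodes, node_world_corners))
  if (is.null(cs)) stop("scene has no nodes")
  list(lo = apply(cs, 2, min), hi = apply(cs, 2, max))
}

#' Point light
#'
#' A single point light for gradient shading. Its shadow map is produced
#' on demand by [render_shadow_map()].
#'
#' @param position world-space light position (mm).
#' @param ambient,diffuse shading coefficients.
#' @param shadow_map_size shadow-map resolution in texels.
#' @return An object of class `voxray_light`.
#' @export
point_light <- function(position, ambient = 0.3, diffuse = 0.7,
                        shadow_map_size = 256L) {
  structure(
    list(position = as.numeric(position), ambient = ambient,
         diffuse = diffuse, shadow_map_size = as.integer(shadow_map_size),
         shadow = NULL),
    class = "voxray_light")
}
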