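#' Paint a sphere of labels into a segmentation mask
#'
#' The scripted stand-in for ad hoc brush segmentation: every voxel
#' whose world-space center lies within `radius` of `center` is set to
#' `label`, overwriting any previous assignment. A list of strokes
#' applied in order emulates an interactive brush session.
#'
#' @param mask a [segmentation_mask()].
#' @param center brush center in world mm.
#' @param radius brush radius in mm (> 0).
#' @param label label to assign, in `1..255` (0 is reserved for
#'   unassigned and cannot be painted).
#' @param pose the companion volume's [affine_pose()] (local mm to
#'   world), identity by default.
#' @param spacing the companion volume's voxel spacing.
#' @return The updated mask.
#' @export
paint_sphere <- function(mask, center, radius, label,
                         pose = affine_pose(), spacing = c(1, 1, 1)) {
  label <- as.integer(label)
  if (label < 1L || label > 255L)
    stop("label must be in 1..255 (0 is reserved for unassigned)")
  if (radius <= 0) stop("radius must be > 0")
  d <- mask$dims
  # local brush geometry: transform the center into the voxel frame and
  # test distances there if the pose is a rigid motion; in general,
  # transform all voxel centers to world (vectorised)
  ctr <- as.numeric(center)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L),
                               k = 0:(d[3] - 1L)))
  loc <- t(t(idx) * spacing)
  w <- loc %*% t(pose$matrix[1:3, 1:3]) +
    matrix(pose$matrix[1:3, 4], nrow(loc), 3, byrow = TRUE)
  inside <- rowSums(sweep(w, 2, ctr)^2) <= radius^2
  if (any(inside)) mask$labels[inside] <- label
  mask
}

#' Tight voxel bounding box of a segment
#'
#' Inclusive 0-based voxel index bounds of all voxels carrying `label`.
#'
#' @param mask a [segmentation_mask()].
#' @param label label in `1..255`.
#' @return List with `lo` and `hi` (integer length-3, `lo <= hi`).
#' @export
segment_aabb <- function(mask, label) {
  label <- as.integer(label)
  if (label < 1L || label > 255L) stop("label must be in 1..255")
  w <- which(mask$labels == label, arr.ind = TRUE)
  if (nrow(w) == 0L)
    stop("label ", label, " is absent from the mask; nothing to extract")
  list(lo = as.integer(apply(w, 2, min)) - 1L,
       hi = as.integer(apply(w, 2, max)) - 1L)
}

#' Extract a segment into a new, independent volume node
#'
#' Implements sub-volume extraction: the segment's voxel AABB (padded by
#' `pad` voxels, clamped to the source extent) is copied out of the
#' source volume into a new node; the new node's mask keeps only the
#' extracted label (other voxels are set to unassigned and hidden via a
#' zero opacity multiplier for label 0, so the new node shows the
#' segment in isolation); the transfer function and render settings are
#' copied; the new node's pose composes the source pose with the AABB
#' offset so the segment initially renders exactly in place; and the
#' segment is hidden from the source volume by setting its segment
#' opacity to 0. The new node is appended to the scene with the next
#' creation index.
#'
#' @param sc a [scene()].
#' @param node_index index of the source node in `sc$nodes`.
#' @param label segment label to extract.
#' @param pad padding in voxels around the AABB (default 1, so trilinear
#'   sampling near the segment boundary has support).
#' @return The updated scene (source hidden segment + appended node).
#' @export
extract_segment <- function(sc, node_index, label, pad = 1L) {
  node <- sc$nodes[[node_index]]
  if (is.null(node$mask)) stop("node has no segmentation mask")
  label <- as.integer(label)
  bb <- segment_aabb(node$mask, label)
  d <- node$volume$dims
  lo <- pmax(bb$lo - as.integer(pad), 0L)
  hi <- pmin(bb$hi + as.integer(pad), d - 1L)
  xs <- (lo[1]:hi[1]) + 1L
  ys <- (lo[2]:hi[2]) + 1L
  zs <- (lo[3]:hi[3]) + 1L
  sub_data <- node$volume$data[xs, ys, zs, drop = FALSE]
  sub_labels <- node$mask$labels[xs, ys, zs, drop = FALSE]
  sub_labels[sub_labels != label] <- 0L
  new_volume <- scalar_volume(sub_data, spacing = node$volume$spacing,
                              name = paste0(node$name, "_seg", label))
  new_mask <- segmentation_mask(sub_labels)
  new_tf <- set_segment_opacity(node$tf, 0L, 0)  # hide unassigned voxels
  new_pose <- pose_compose(node$pose,
                           pose_translation(lo * node$volume$spacing))
  new_node <- volume_node(new_volume, new_tf, mask = new_mask,
                          pose = new_pose, visible = node$visible,
                          name = new_volume$name)
  # hide the segment from the source (data are never modified)
  node$tf <- set_segment_opacity(node$tf, label, 0)
  node$skip_grid <- NULL  # opacity change invalidates the cached grid decision
  sc$nodes[[node_index]] <- node
  scene_add_node(sc, new_node)
}

#' Extract every segment of a node into separate volumes
#'
#' Applies [extract_segment()] to each distinct nonzero label of the
#' node's mask, in ascending label order. A mask with k labels turns a
#' single-volume scene into a scene of k + 1 volumes.
#'
#' @inheritParams extract_segment
#' @return The updated scene.
#' @export
extract_all_segments <- function(sc, node_index, pad = 1L) {
  node <- sc$nodes[[node_index]]
  if (is.null(node$mask)) stop("node has no segmentation mask")
  labs <- sort(unique(as.vector(node$mask$labels)))
  labs <- labs[labs > 0L]
  for (lb in labs) sc <- extract_segment(sc, node_index, lb, pad = pad)
  sc
}
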