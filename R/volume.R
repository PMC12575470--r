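#' Scalar intensity volume
#'
#' A 3D grid of scalar intensities (arbitrary units, typically
#' Hounsfield-like) with per-axis voxel spacing. Voxel centers sit at
#' integer voxel coordinates `0 .. dim - 1`; the renderable local box is
#' `[-0.5, dim - 0.5] * spacing` per axis, so trilinear interpolation is
#' defined everywhere inside the box via boundary clamping.
#'
#' @param data numeric 3D array of intensities (finite).
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param name identifier used in logs.
#' @return An object of class `voxray_volume` with fields `data`,
#'   `dims`, `spacing`, `name`.
#' @examples
#' v <- scalar_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' v$dims
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), name = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data))) stop("`data` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  storage.mode(data) <- "double"
  structure(
    list(data = data, dims = dim(data), spacing = spacing,
         name = as.character(name)[1]),
    class = "voxray_volume")
}

#' @export
print.voxray_volume <- function(x, ...) {
  cat(sprintf("<voxray_volume '%s'> %d x %d x %d voxels, spacing %s mm, range [%.6g, %.6g]\n",
              x$name, x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Segmentation mask
#'
#' An 8-bit label grid co-registered with a volume: one label in
#' `0..255` per voxel, where 0 means unassigned. Labels divide a volume
#' into sub-volumes that can be hidden or extracted independently.
#'
#' @param labels integer 3D array of labels in `[0, 255]`. A scalar 0
#'   together with `dims` creates an empty (all-unassigned) mask.
#' @param dims voxel counts, required when `labels` is scalar.
#' @return An object of class `voxray_mask` with fields `labels`, `dims`.
#' @examples
#' m <- segmentation_mask(dims = c(8, 8, 8))
#' table(m$labels)
#' @export
segmentation_mask <- function(labels = 0L, dims = NULL) {
  if (!is.array(labels)) {
    if (is.null(dims)) stop("`dims` required when `labels` is not an array")
    labels <- array(as.integer(labels), dim = dims)
  }
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  if (any(labels < 0L) || any(labels > 255L))
    stop("labels must be in [0, 255] (8-bit, 0 = unassigned)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, dims = dim(labels)), class = "voxray_mask")
}

#' @export
print.voxray_mask <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  labs <- labs[labs > 0L]
  cat(sprintf("<voxray_mask> %d x %d x %d voxels, %d segment(s)%s\n",
              x$dims[1], x$dims[2], x$dims[3], length(labs),
              if (length(labs)) paste0(": ", paste(labs, collapse = " ")) else ""))
  invisible(x)
}

stopifnot_mask_matches <- function(mask, volume) {
  if (!is.null(mask) && !identical(mask$dims, volume$dims))
    stop("mask dims (", paste(mask$dims, collapse = "x"),
         ") do not match volume dims (", paste(volume$dims, collapse = "x"), ")")
  invisible(TRUE)
}

#' Sample a volume at continuous voxel coordinates
#'
#' Trilinear interpolation of the eight surrounding voxel values, with
#' voxel centers at integer coordinates `0 .. dim - 1`. Coordinates
#' outside the grid are clamped to the boundary voxel, so the value is
#' defined on the whole sampling box `[-0.5, dim - 0.5]` (and beyond).
#'
#' @param volume a [scalar_volume()].
#' @param p numeric length-3 point, or an n x 3 matrix of points, in
#'   continuous 0-based voxel coordinates.
#' @return Interpolated intensity (vector of length n).
#' @examples
#' v <- scalar_volume(array(seq_len(8), c(2, 2, 2)))
#' sample_intensity(v, c(0.5, 0, 0))  # midway between voxels 1 and 2
#' @export
sample_intensity <- function(volume, p) {
  p <- to_point_matrix(p)
  cpp_sample_trilinear(as.double(volume$data), as.integer(volume$dims), p)
}

#' Sample a segmentation mask at continuous voxel coordinates
#'
#' Nearest-neighbor lookup (labels are categorical and must never be
#' interpolated): each coordinate is rounded to the nearest voxel
#' center. Points outside the grid return 0 (unassigned).
#'
#' @param mask a [segmentation_mask()].
#' @param p numeric length-3 point or n x 3 matrix, 0-based voxel
#'   coordinates.
#' @return Integer label(s).
#' @export
sample_label <- function(mask, p) {
  p <- to_point_matrix(p)
  cpp_sample_label(mask$labels, as.integer(mask$dims), p)
}

to_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("point matrix must have 3 columns")
    storage.mode(p) <- "double"
    p
  } else {
    if (length(p) != 3L) stop("a point must have 3 coordinates")
    matrix(as.double(p), nrow = 1L)
  }
}
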