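#' Affine pose (local mm to world mm)
#'
#' A 4x4 homogeneous transform mapping a node's local millimetre frame
#' (voxel index times spacing) into world space. Poses let extracted
#' sub-volumes be moved freely within the scene.
#'
#' @param matrix a 4x4 matrix with bottom row `(0, 0, 0, 1)`; must be
#'   invertible.
#' @return An object of class `voxray_pose`.
#' @seealso [pose_translation()], [pose_rotation()], [pose_compose()]
#' @export
affine_pose <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!identical(dim(matrix), c(4L, 4L))) stop("pose matrix must be 4x4")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("pose bottom row must be (0, 0, 0, 1)")
  d <- det(matrix[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) stop("pose matrix is singular")
  structure(list(matrix = matrix), class = "voxray_pose")
}

#' @export
print.voxray_pose <- function(x, ...) {
  cat("<voxray_pose>\n")
  print(x$matrix)
  invisible(x)
}

#' @rdname affine_pose
#' @param t translation vector (mm).
#' @export
pose_translation <- function(t) {
  m <- diag(4)
  m[1:3, 4] <- as.numeric(t)
  affine_pose(m)
}

#' @rdname affine_pose
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @export
pose_rotation <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c3 <- cos(a); s3 <- sin(a)
  r <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, c3, -s3), c(0, s3, c3)),
    y = rbind(c(c3, 0, s3), c(0, 1, 0), c(-s3, 0, c3)),
    z = rbind(c(c3, -s3, 0), c(s3, c3, 0), c(0, 0, 1)))
  m <- diag(4)
  m[1:3, 1:3] <- r
  affine_pose(m)
}

#' @rdname affine_pose
#' @param ... poses, applied right to left (the last argument acts first).
#' @export
pose_compose <- function(...) {
  ps <- list(...)
  m <- diag(4)
  for (p in ps) m <- m %*% p$matrix
  affine_pose(m)
}

#' Apply an affine pose to a point
#'
#' Transforms a homogeneous 3D point by the pose (or its inverse).
#'
#' @param pose a [affine_pose()].
#' @param point numeric length-3 point.
#' @param inverse apply the inverse transform instead.
#' @return Transformed length-3 point.
#' @examples
#' transform_point(pose_translation(c(10, 0, 0)), c(1, 2, 3))
#' @export
transform_point <- function(pose, point, inverse = FALSE) {
  m <- if (inverse) solve(pose$matrix) else pose$matrix
  as.numeric(m %*% c(as.numeric(point), 1))[1:3]
}
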