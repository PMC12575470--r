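#' Perspective camera
#'
#' Pinhole camera defined by an eye position, an orthonormal
#' (right, up, forward) basis, a vertical field of view, an image size
#' and near/far clip distances. Pixel `(0, 0)` is the top-left pixel;
#' rays go through pixel centers.
#'
#' @param eye eye position (world mm).
#' @param right,up,forward orthonormal camera axes (world).
#' @param vfov vertical field of view in degrees, in `(0, 180)`.
#' @param image_size `c(width, height)` in pixels.
#' @param near,far clip distances (mm), `0 < near < far`.
#' @return An object of class `voxray_camera`.
#' @seealso [camera_look_at()] for the usual constructor.
#' @export
camera <- function(eye, right, up, forward, vfov = 45,
                   image_size = c(128, 128), near = 1, far = 1000) {
  eye <- as.numeric(eye); right <- as.numeric(right)
  up <- as.numeric(up); forward <- as.numeric(forward)
  if (vfov <= 0 || vfov >= 180) stop("vfov must be in (0, 180) degrees")
  if (!(near > 0 && near < far)) stop("need 0 < near < far")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 1L))
    stop("image_size must be c(width, height), both >= 1")
  b <- rbind(right, up, forward)
  if (max(abs(b %*% t(b) - diag(3))) > 1e-8)
    stop("camera axes must be orthonormal")
  structure(
    list(eye = eye, right = right, up = up, forward = forward,
         vfov = as.numeric(vfov), image_size = image_size,
         near = as.numeric(near), far = as.numeric(far)),
    class = "voxray_camera")
}

#' @export
print.voxray_camera <- function(x, ...) {
  cat(sprintf("<voxray_camera> %d x %d px, vfov %g deg, near %g / far %g mm, eye (%s)\n",
              x$image_size[1], x$image_size[2], x$vfov, x$near, x$far,
              paste(format(x$eye, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Look-at camera constructor
#'
#' Builds an orthonormal camera basis from an eye point, a target point
#' and an approximate up vector.
#'
#' @param eye eye position (world mm).
#' @param target point the camera looks at.
#' @param up approximate up direction (re-orthogonalised).
#' @inheritParams camera
#' @return A [camera()].
#' @export
camera_look_at <- function(eye, target, up = c(0, 0, 1), vfov = 45,
                           image_size = c(128, 128), near = 1, far = 1000) {
  fwd <- as.numeric(target) - as.numeric(eye)
  nf <- sqrt(sum(fwd^2))
  if (nf < 1e-12) stop("eye and target coincide")
  fwd <- fwd / nf
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  nr <- sqrt(sum(right^2))
  if (nr < 1e-12) stop("up vector is parallel to the view direction")
  right <- right / nr
  upv <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])
  camera(eye, right, upv, fwd, vfov = vfov, image_size = image_size,
         near = near, far = far)
}

# Flat list representation handed to the C++ kernels.
camera_internal <- function(cam) {
  list(eye = cam$eye, right = cam$right, up = cam$up, forward = cam$forward,
       tanv = tan(cam$vfov / 2 * pi / 180),
       aspect = cam$image_size[1] / cam$image_size[2],
       width = cam$image_size[1], height = cam$image_size[2],
       near = cam$near, far = cam$far)
}

#' Generate the camera ray through a pixel
#'
#' Returns the ray through the center of pixel `(ix, iy)` (0-based,
#' `(0, 0)` top-left), with unit world direction and the camera's
#' near/far distances as the ray's clip interval.
#'
#' @param cam a [camera()].
#' @param pixel integer `c(ix, iy)`, `0 <= ix < width`, `0 <= iy < height`.
#' @return A `voxray_ray`: list with `origin`, `direction`, `t_near`,
#'   `t_far`.
#' @export
generate_ray <- function(cam, pixel) {
  ix <- as.integer(pixel[1]); iy <- as.integer(pixel[2])
  if (ix < 0L || iy < 0L || ix >= cam$image_size[1] || iy >= cam$image_size[2])
    stop("pixel (", ix, ", ", iy, ") outside the image")
  d <- cpp_pixel_rays(camera_internal(cam), ix, iy)
  structure(
    list(origin = cam$eye, direction = as.numeric(d[1, ]),
         t_near = cam$near, t_far = cam$far),
    class = "voxray_ray")
}

# Per-pixel conversion factor between camera-space z and ray distance:
# t = z / (direction . forward). Returns the H x W matrix of
# 1 / cos(angle between ray and forward).
ray_distance_factors <- function(cam) {
  W <- cam$image_size[1]; H <- cam$image_size[2]
  ix <- rep(0:(W - 1L), each = H)
  iy <- rep(0:(H - 1L), times = W)
  d <- cpp_pixel_rays(camera_internal(cam), ix, iy)
  ddotf <- d %*% cam$forward
  matrix(1 / ddotf, nrow = H, ncol = W)
}
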