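#' Compare two rendered images
#'
#' Reports the maximum and mean per-channel absolute difference and the
#' number of differing pixels between two renders (arrays, render
#' objects, or PNG file paths).
#'
#' @param a,b H x W x C arrays, `voxray_render` objects, or PNG paths.
#' @param tol per-channel tolerance below which values count as equal
#'   (default 0: exact comparison).
#' @return List with `max_diff`, `mean_diff`, `n_diff_pixels`,
#'   `n_pixels`.
#' @export
compare_images <- function(a, b, tol = 0) {
  a <- as_image_array(a)
  b <- as_image_array(b)
  if (!identical(dim(a), dim(b)))
    stop("image dimensions differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  d <- abs(a - b)
  per_pixel <- apply(d, c(1, 2), max)
  list(max_diff = max(d), mean_diff = mean(d),
       n_diff_pixels = sum(per_pixel > tol),
       n_pixels = length(per_pixel))
}

as_image_array <- function(x) {
  if (is.character(x)) return(read_image(x))
  if (inherits(x, "voxray_render")) return(x$color)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  if (is.array(x)) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an image")
}
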