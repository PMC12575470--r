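#' Transfer function
#'
#' Maps voxel intensity to color and opacity, with per-segment opacity
#' multipliers. Stored alphas are calibrated for a sampling interval of
#' `reference_step` mm; [classify()] rescales them to the actual step via
#' the exponential transmittance relation
#' `alpha' = 1 - (1 - alpha)^(step / reference_step)`.
#'
#' Hiding a segment is done by setting its opacity multiplier to 0; the
#' voxel data themselves are never modified.
#'
#' @param intensities strictly increasing control-point intensities
#'   (at least 2).
#' @param colors n x 4 matrix of RGBA control values; alpha in `[0, 1]`.
#' @param segment_opacity numeric vector of 256 multipliers in `[0, 1]`
#'   indexed by label `0..255` (position 1 = label 0), or a named vector
#'   like `c("3" = 0)` overriding the default of 1.
#' @param reference_step sampling interval (mm) at which the stored
#'   alphas are calibrated.
#' @param interpolation `"linear"` for piecewise-linear interpolation
#'   between control points, or `"constant"` for a left-constant step
#'   function (the value of the control point at or below the
#'   intensity). Constant interpolation gives exactly binary opacities
#'   for threshold-style transfer functions. Evaluation outside the
#'   control-point domain clamps to the end values either way.
#' @return An object of class `voxray_tf`.
#' @seealso [classify()], [tf_preset()], [set_segment_opacity()]
#' @export
transfer_function <- function(intensities, colors,
                              segment_opacity = NULL,
                              reference_step = 1,
                              interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  intensities <- as.numeric(intensities)
  if (length(intensities) < 2L) stop("need at least 2 control points")
  if (any(diff(intensities) <= 0))
    stop("control-point intensities must be strictly increasing")
  colors <- as.matrix(colors)
  if (nrow(colors) != length(intensities) || ncol(colors) != 4L)
    stop("`colors` must be an n x 4 RGBA matrix matching `intensities`")
  if (any(colors[, 4] < 0) || any(colors[, 4] > 1))
    stop("alpha control values must be in [0, 1]")
  segop <- rep(1, 256)
  if (!is.null(segment_opacity)) {
    if (!is.null(names(segment_opacity))) {
      idx <- as.integer(names(segment_opacity))
      if (any(is.na(idx)) || any(idx < 0L) || any(idx > 255L))
        stop("segment_opacity names must be labels in 0..255")
      segop[idx + 1L] <- as.numeric(segment_opacity)
    } else {
      if (length(segment_opacity) != 256L)
        stop("unnamed segment_opacity must have length 256")
      segop <- as.numeric(segment_opacity)
    }
  }
  if (any(segop < 0) || any(segop > 1))
    stop("segment opacity multipliers must be in [0, 1]")
  if (reference_step <= 0) stop("reference_step must be > 0")
  structure(
    list(intensities = intensities, colors = unname(colors),
         segment_opacity = segop, reference_step = as.numeric(reference_step),
         interpolation = interpolation),
    class = "voxray_tf")
}

#' @export
print.voxray_tf <- function(x, ...) {
  hidden <- which(x$segment_opacity == 0) - 1L
  cat(sprintf("<voxray_tf> %d control points over [%g, %g], %s interpolation, reference step %g mm%s\n",
              length(x$intensities), x$intensities[1],
              x$intensities[length(x$intensities)], x$interpolation,
              x$reference_step,
              if (length(hidden)) paste0("; hidden labels: ", paste(hidden, collapse = " ")) else ""))
  invisible(x)
}

#' Set a per-segment opacity multiplier
#'
#' @param tf a [transfer_function()].
#' @param label label in `0..255`.
#' @param opacity multiplier in `[0, 1]`; 0 hides the segment.
#' @return The modified transfer function.
#' @export
set_segment_opacity <- function(tf, label, opacity) {
  label <- as.integer(label)
  if (any(label < 0L) || any(label > 255L)) stop("label must be in 0..255")
  if (any(opacity < 0) || any(opacity > 1)) stop("opacity must be in [0, 1]")
  tf$segment_opacity[label + 1L] <- opacity
  tf
}

#' Transfer-function presets
#'
#' * `"bone_binary"`: left-constant step function, fully opaque bone
#'   color at and above `threshold`, fully transparent below. Per-sample
#'   opacity is exactly 0 or 1, which makes multi-pass and one-pass
#'   rendering agree bit-exactly.
#' * `"bone"`: piecewise-linear ramp from transparent at
#'   `threshold - 150` to semi-opaque (alpha 0.6) bone at `threshold + 100`.
#' * `"soft"`: faint reddish ramp over soft-tissue intensities.
#'
#' @param name preset name.
#' @param threshold bone intensity threshold (defaults to 300, between
#'   the phantoms' soft-tissue and bone modes).
#' @param color RGB used for the opaque end.
#' @return A [transfer_function()].
#' @export
tf_preset <- function(name = c("bone_binary", "bone", "soft"),
                      threshold = 300, color = c(0.95, 0.91, 0.83)) {
  name <- match.arg(name)
  switch(name,
    bone_binary = transfer_function(
      c(-2000, threshold),
      rbind(c(0, 0, 0, 0), c(color, 1)),
      interpolation = "constant"),
    bone = transfer_function(
      c(threshold - 150, threshold + 100),
      rbind(c(color * 0.4, 0), c(color, 0.6))),
    soft = transfer_function(
      c(0, 120),
      rbind(c(0.4, 0.1, 0.1, 0), c(0.8, 0.4, 0.35, 0.12))))
}

# Raw RGBA of the transfer function at given intensities (no segment
# multiplier, no step correction).
tf_eval <- function(tf, intensity) {
  x <- tf$intensities
  n <- length(x)
  i <- findInterval(intensity, x)  # 0 .. n
  out <- matrix(0, length(intensity), 4)
  below <- i == 0L
  above <- i >= n
  mid <- !below & !above
  if (any(below)) out[below, ] <- matrix(tf$colors[1, ], sum(below), 4, byrow = TRUE)
  if (any(above)) out[above, ] <- matrix(tf$colors[n, ], sum(above), 4, byrow = TRUE)
  if (any(mid)) {
    ii <- i[mid]
    if (tf$interpolation == "constant") {
      out[mid, ] <- tf$colors[ii, , drop = FALSE]
    } else {
      w <- (intensity[mid] - x[ii]) / (x[ii + 1L] - x[ii])
      out[mid, ] <- tf$colors[ii, , drop = FALSE] * (1 - w) +
        tf$colors[ii + 1L, , drop = FALSE] * w
    }
  }
  colnames(out) <- c("r", "g", "b", "a")
  out
}

#' Classify a sample
#'
#' Evaluates the transfer function at an intensity, multiplies the alpha
#' by the segment-opacity multiplier of the sample's label, and applies
#' the step-size opacity correction
#' `alpha' = 1 - (1 - alpha)^(step / reference_step)` so that accumulated
#' opacity is invariant under step refinement of a homogeneous medium.
#'
#' @param tf a [transfer_function()].
#' @param intensity sampled intensity (vectorised).
#' @param label segment label(s) in `0..255` (default 0, unassigned).
#' @param step sampling interval in mm (> 0).
#' @return n x 4 RGBA matrix with step-corrected alpha.
#' @examples
#' tf <- tf_preset("bone_binary")
#' classify(tf, c(100, 500), step = 1)[, "a"]
#' @export
classify <- function(tf, intensity, label = 0L, step = tf$reference_step) {
  if (any(step <= 0)) stop("step must be > 0")
  label <- as.integer(label)
  if (any(label < 0L) || any(label > 255L)) stop("label must be in 0..255")
  out <- tf_eval(tf, intensity)
  a <- out[, 4] * tf$segment_opacity[label + 1L]
  out[, 4] <- 1 - (1 - a)^(step / tf$reference_step)
  out
}

# Maximum raw TF alpha attainable on the intensity interval [lo, hi]
# (used to decide whether an empty-space-skipping block is provably
# transparent). Exact for both interpolation modes: the maximum of a
# piecewise-linear (or step) function on an interval is attained at an
# endpoint or at an interior control point.
tf_max_alpha <- function(tf, lo, hi) {
  xs <- tf$intensities
  cand <- c(lo, hi, xs[xs >= lo & xs <= hi])
  if (tf$interpolation == "constant") {
    # value on [x_i, x_{i+1}) is the left control's alpha; also probe
    # just past each control point inside the range
    cand <- c(cand, xs[xs >= lo & xs < hi])
  }
  max(tf_eval(tf, cand)[, 4])
}
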