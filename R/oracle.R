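#' One-pass reference renderer
#'
#' The simple, slow ground truth the multi-pass renderer is checked
#' against: a single ray march per pixel on the global grid
#' `t = k * step` from the eye over `[near, far)`, where at every step
#' the sample of every visible volume whose box contains the point is
#' classified and composited front-to-back in node-list order before
#' advancing. Early ray termination applies to the jointly accumulated
#' opacity; the depth is the first distance at which the threshold is
#' reached, the far distance otherwise. Background and opaque-layer
#' resolution are identical to [render_scene()]. Screen rectangles and
#' empty-space skipping are deliberately omitted.
#'
#' For scenes whose transfer functions classify every sample as fully
#' opaque or fully transparent (e.g. the `"bone_binary"` preset),
#' [render_scene()] with `align_global_grid = TRUE` matches this
#' renderer bit-exactly in color and depth. With semi-transparent,
#' cross-volume-interleaving classifications the two renderers differ:
#' that limitation is inherent to sequential per-volume compositing.
#'
#' @param sc a [scene()].
#' @param cam a [camera()].
#' @param params a [render_params()]; only `step` and `alpha_threshold`
#'   are used (plus `shading`).
#' @return A `voxray_render` (same contract as [render_scene()]).
#' @export
render_onepass <- function(sc, cam, params = render_params()) {
  fb <- make_framebuffer(cam, sc)
  nodes <- Filter(function(n) n$visible, sc$nodes)
  params$step <- if (length(nodes)) resolve_step(params, sc) else 1
  params$skip <- FALSE
  pr <- params_internal(params, params$step, if (params$shading) sc$light else NULL)
  if (length(nodes)) {
    ni <- lapply(nodes, node_internal, params = params, step = params$step)
    out <- cpp_render_onepass(ni, camera_internal(cam), pr, fb$depth)
    Ap <- out$color[, , 4]
    fb$color <- out$color + as.vector(1 - Ap) * fb$color
    fb <- blit_depth(fb, out$depth)
  }
  res <- list(color = resolve_framebuffer(fb),
              alpha = fb$color[, , 4],
              depth = fb$depth,
              camera = cam, params = params)
  class(res) <- "voxray_render"
  res
}
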