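# Scene description files: a small YAML schema gathering volume/mask
# paths, transfer functions, node poses, the camera, an optional light,
# render parameters and output paths. Unknown keys are rejected so
# typos fail loudly.

scene_config_keys <- list(
  top = c("volumes", "camera", "background", "light", "params",
          "opaque_layer", "output"),
  volume = c("path", "mask", "tf", "segment_opacity", "translation",
             "rotation_deg", "visible", "name"),
  camera = c("eye", "look_at", "up", "vfov", "size", "near", "far"),
  light = c("position", "ambient", "diffuse", "shadow_map_size"),
  params = c("step", "alpha_threshold", "align_global_grid", "shading",
             "skip", "block_size"),
  tf = c("preset", "threshold", "color", "points", "reference_step",
         "interpolation"),
  opaque_layer = c("color", "depth"),
  output = c("color", "depth"))

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Load a scene configuration file
#'
#' Reads a YAML scene description and assembles the scene, camera and
#' render parameters. Referenced volume/mask files are loaded with
#' [read_volume()]; file paths are resolved relative to the config
#' file's directory. Omitted optional fields get defaults; unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return List with `scene`, `camera`, `params` and `output` (a list
#'   with optional `color`/`depth` paths, possibly empty).
#' @export
load_scene_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, scene_config_keys$top, "scene config")
  base <- dirname(path)
  rel <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  if (is.null(cfg$volumes) || !length(cfg$volumes))
    stop("scene config must list at least one volume")
  nodes <- lapply(seq_along(cfg$volumes), function(i) {
    vb <- cfg$volumes[[i]]
    check_keys(vb, scene_config_keys$volume, sprintf("volumes[%d]", i))
    if (is.null(vb$path)) stop(sprintf("volumes[%d]: missing 'path'", i))
    vol <- read_volume(rel(vb$path))
    mask <- if (!is.null(vb$mask)) read_volume(rel(vb$mask), as_mask = TRUE)
    tf <- config_tf(vb$tf, sprintf("volumes[%d]$tf", i))
    if (!is.null(vb$segment_opacity)) {
      for (k in names(vb$segment_opacity))
        tf <- set_segment_opacity(tf, as.integer(k), vb$segment_opacity[[k]])
    }
    pose <- attr(vol, "pose")
    if (is.null(pose)) pose <- affine_pose()
    if (!is.null(vb$rotation_deg)) {
      r <- as.numeric(vb$rotation_deg)
      pose <- pose_compose(pose_rotation("z", r[3]), pose_rotation("y", r[2]),
                           pose_rotation("x", r[1]), pose)
    }
    if (!is.null(vb$translation))
      pose <- pose_compose(pose_translation(as.numeric(vb$translation)), pose)
    volume_node(vol, tf, mask = mask, pose = pose,
                visible = if (is.null(vb$visible)) TRUE else isTRUE(vb$visible),
                name = if (is.null(vb$name)) vol$name else vb$name)
  })
  light <- NULL
  if (!is.null(cfg$light)) {
    check_keys(cfg$light, scene_config_keys$light, "light")
    if (is.null(cfg$light$position)) stop("light: missing 'position'")
    light <- point_light(as.numeric(cfg$light$position),
      ambient = if (is.null(cfg$light$ambient)) 0.3 else cfg$light$ambient,
      diffuse = if (is.null(cfg$light$diffuse)) 0.7 else cfg$light$diffuse,
      shadow_map_size = if (is.null(cfg$light$shadow_map_size)) 256L
                        else as.integer(cfg$light$shadow_map_size))
  }
  opaque <- NULL
  if (!is.null(cfg$opaque_layer)) {
    check_keys(cfg$opaque_layer, scene_config_keys$opaque_layer, "opaque_layer")
    opaque <- list(color = read_image(rel(cfg$opaque_layer$color)),
                   depth = read_pfm(rel(cfg$opaque_layer$depth)))
  }
  sc <- scene(nodes,
              background = if (is.null(cfg$background)) c(0, 0, 0)
                           else as.numeric(cfg$background),
              light = light, opaque_layer = opaque)
  cb <- if (is.null(cfg$camera)) list() else cfg$camera
  check_keys(cb, scene_config_keys$camera, "camera")
  bounds <- scene_world_bounds(sc)
  ctr <- (bounds$lo + bounds$hi) / 2
  ext <- max(bounds$hi - bounds$lo)
  cam <- camera_look_at(
    eye = if (is.null(cb$eye)) ctr + c(0.5, -2, 0.5) * ext else as.numeric(cb$eye),
    target = if (is.null(cb$look_at)) ctr else as.numeric(cb$look_at),
    up = if (is.null(cb$up)) c(0, 0, 1) else as.numeric(cb$up),
    vfov = if (is.null(cb$vfov)) 45 else cb$vfov,
    image_size = if (is.null(cb$size)) c(128L, 128L) else as.integer(cb$size),
    near = if (is.null(cb$near)) 1 else cb$near,
    far = if (is.null(cb$far)) 8 * max(ext, 1) else cb$far)
  pb <- if (is.null(cfg$params)) list() else cfg$params
  check_keys(pb, scene_config_keys$params, "params")
  params <- render_params(
    step = pb$step,
    alpha_threshold = if (is.null(pb$alpha_threshold)) 0.99 else pb$alpha_threshold,
    align_global_grid = isTRUE(pb$align_global_grid),
    shading = isTRUE(pb$shading),
    skip = if (is.null(pb$skip)) TRUE else isTRUE(pb$skip),
    block_size = if (is.null(pb$block_size)) 8L else as.integer(pb$block_size))
  output <- list()
  if (!is.null(cfg$output)) {
    check_keys(cfg$output, scene_config_keys$output, "output")
    output <- cfg$output
  }
  list(scene = sc, camera = cam, params = params, output = output)
}

config_tf <- function(block, where) {
  if (is.null(block)) return(tf_preset("bone_binary"))
  if (is.character(block) && length(block) == 1L) return(tf_preset(block))
  check_keys(block, scene_config_keys$tf, where)
  if (!is.null(block$preset)) {
    args <- list(name = block$preset)
    if (!is.null(block$threshold)) args$threshold <- block$threshold
    if (!is.null(block$color)) args$color <- as.numeric(block$color)
    return(do.call(tf_preset, args))
  }
  if (is.null(block$points)) stop(where, ": need 'preset' or 'points'")
  pts <- do.call(rbind, lapply(block$points, as.numeric))
  if (ncol(pts) != 5L)
    stop(where, ": each control point must be (intensity, r, g, b, alpha)")
  transfer_function(
    pts[, 1], pts[, 2:5, drop = FALSE],
    reference_step = if (is.null(block$reference_step)) 1 else block$reference_step,
    interpolation = if (is.null(block$interpolation)) "linear" else block$interpolation)
}
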