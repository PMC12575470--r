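# Deterministic procedural phantoms standing in for the three CT use
# cases the renderer targets: a scoliotic spine divided into vertebra
# segments, a skull with a circular keyhole (craniotomy) segment, and a
# skull shell broken into fragments. Intensities are on a CT-like scale
# (soft tissue ~40, bone ~700) so the bundled transfer-function presets
# apply directly.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

voxel_grid <- function(dims) {
  list(x = array(rep(0:(dims[1] - 1L), times = dims[2] * dims[3]), dims),
       y = array(rep(rep(0:(dims[2] - 1L), each = dims[1]), times = dims[3]), dims),
       z = array(rep(0:(dims[3] - 1L), each = dims[1] * dims[2]), dims))
}

#' Generate a procedural medical-style phantom
#'
#' Deterministic (seeded) phantoms with co-registered segmentation
#' masks, emulating three surgical-planning use cases:
#'
#' * `"spine"`: a laterally curved stack of 19 bright ellipsoidal
#'   vertebra bodies with posterior protrusions (C6, C7, T1-T12, L1-L5)
#'   plus one combined shoulder-girdle bar, in a dim soft-tissue noise
#'   field; 20 labels, one per segment.
#' * `"keyhole_skull"`: a bright spherical bone shell with a single
#'   labeled circular disk segment punched through it (label 1).
#' * `"fracture"`: the bright shell partitioned into `k` labeled
#'   fragments by the bisecting planes of `k` seeded random directions
#'   (a spherical Voronoi partition, so each fragment is connected).
#'
#' Soft tissue is ~40 +/- 10 and bone ~700 +/- 30 intensity units, so a
#' threshold near 300 separates the two modes cleanly.
#'
#' @param kind phantom kind.
#' @param dims voxel counts (default 64 x 64 x 96 for the spine,
#'   64^3 otherwise).
#' @param seed integer fixing all randomness.
#' @param n_fragments fragment count for `"fracture"` (default 5).
#' @param keyhole_radius keyhole disk radius in voxels (default 7).
#' @return List with `volume` (a [scalar_volume()]) and `mask`
#'   (a [segmentation_mask()]).
#' @export
generate_phantom <- function(kind = c("spine", "keyhole_skull", "fracture"),
                             dims = NULL, seed = 0L, n_fragments = 5L,
                             keyhole_radius = 7) {
  kind <- match.arg(kind)
  if (is.null(dims)) dims <- if (kind == "spine") c(64L, 64L, 96L) else c(64L, 64L, 64L)
  dims <- as.integer(dims)
  if (any(dims < 32L)) stop("phantom dims must be >= 32 per axis")
  local_seed(seed, {
    g <- voxel_grid(dims)
    intensity <- array(40 + 10 * rnorm(prod(dims)), dims)
    bone_noise <- array(30 * rnorm(prod(dims)), dims)
    labels <- array(0L, dims)
    sx <- (dims[1] - 1) / 2
    sy <- (dims[2] - 1) / 2
    if (kind == "spine") {
      nvert <- 19L
      zc <- seq(6, dims[3] - 12, length.out = nvert)
      amp <- dims[1] / 10
      for (i in seq_len(nvert)) {
        cx <- sx + amp * sin(2 * pi * zc[i] / dims[3])
        body <- ((g$x - cx) / 6)^2 + ((g$y - sy) / 5)^2 + ((g$z - zc[i]) / 1.9)^2 <= 1
        proc <- ((g$x - cx) / 2)^2 + ((g$y - (sy + 7)) / 4.5)^2 + ((g$z - zc[i]) / 1.5)^2 <= 1
        seg <- body | proc
        labels[seg] <- i
        intensity[seg] <- 700 + bone_noise[seg]
      }
      girdle <- ((g$x - sx) / (sx * 0.62))^2 + ((g$y - (sy - 6)) / 4)^2 +
        ((g$z - (dims[3] - 6)) / 2.4)^2 <= 1
      labels[girdle] <- 20L
      intensity[girdle] <- 700 + bone_noise[girdle]
    } else {
      sz <- (dims[3] - 1) / 2
      r_out <- min(dims) * 0.38
      r_in <- r_out - 5
      dx <- g$x - sx; dy <- g$y - sy; dz <- g$z - sz
      r <- sqrt(dx^2 + dy^2 + dz^2)
      shell <- r >= r_in & r <= r_out
      intensity[shell] <- 700 + bone_noise[shell]
      if (kind == "keyhole_skull") {
        # disk punched through the anterior (-y) side of the shell
        hole <- shell & dy < 0 & sqrt(dx^2 + dz^2) <= keyhole_radius
        labels[hole] <- 1L
      } else {
        k <- as.integer(n_fragments)
        if (k < 1L || k > 255L) stop("n_fragments must be in 1..255")
        dirs <- matrix(rnorm(3 * k), k, 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        idx <- which(shell)
        u <- cbind(dx[idx], dy[idx], dz[idx])
        dots <- u %*% t(dirs)
        labels[idx] <- max.col(dots, ties.method = "first")
      }
    }
    list(volume = scalar_volume(intensity, name = kind),
         mask = segmentation_mask(labels))
  })
}

#' Single-phantom scene with a default camera
#'
#' Convenience wrapper: generates a phantom, wraps it in a one-node
#' scene with the binary bone transfer function, and aims a camera at
#' the volume center.
#'
#' @inheritParams generate_phantom
#' @param tf transfer function (default [tf_preset]`("bone_binary")`).
#' @param image_size camera image size in pixels.
#' @param ... further arguments passed to [generate_phantom()].
#' @return List with `scene`, `camera`, `volume`, `mask`.
#' @export
phantom_scene <- function(kind = c("spine", "keyhole_skull", "fracture"),
                          dims = NULL, seed = 0L,
                          tf = tf_preset("bone_binary"),
                          image_size = c(128, 128), ...) {
  kind <- match.arg(kind)
  ph <- generate_phantom(kind, dims = dims, seed = seed, ...)
  ctr_local <- (ph$volume$dims - 1) / 2 * ph$volume$spacing
  pose <- pose_translation(-ctr_local)  # volume centered at the origin
  node <- volume_node(ph$volume, tf, mask = ph$mask, pose = pose, name = kind)
  sc <- scene(node)
  ext <- max(ph$volume$dims * ph$volume$spacing)
  eye <- c(0.4, -2.2, 0.45) / sqrt(0.4^2 + 2.2^2 + 0.45^2) * ext * 1.6
  cam <- camera_look_at(eye, c(0, 0, 0), vfov = 45,
                        image_size = image_size, near = 1, far = 6 * ext)
  list(scene = sc, camera = cam, volume = ph$volume, mask = ph$mask)
}

#' Random scene of disjoint binary-opaque blob volumes
#'
#' Builds `n` small independent volumes, each containing one bright
#' ellipsoid in a soft-tissue noise field, posed with random rotations
#' and jittered grid positions so that their bounding boxes overlap
#' while their opaque (bone) voxel sets stay pairwise disjoint. Each
#' node uses a binary (left-constant) transfer function with its own
#' color, so every sample classifies as exactly opaque or exactly
#' transparent. These are the study scenes for checking the multi-pass
#' renderer against the one-pass reference bit-for-bit.
#'
#' @param n number of volumes, 2..8.
#' @param seed integer seed.
#' @param image_size camera image size.
#' @return List with `scene` and `camera`.
#' @export
random_blob_scene <- function(n, seed = 0L, image_size = c(128, 128)) {
  n <- as.integer(n)
  if (n < 1L || n > 8L) stop("n must be in 1..8")
  local_seed(seed, {
    base <- as.matrix(expand.grid(x = c(-10, 10), y = c(-10, 10),
                                  z = c(-10, 10)))[seq_len(n), , drop = FALSE]
    cols <- rbind(c(0.9, 0.3, 0.2), c(0.2, 0.8, 0.3), c(0.25, 0.4, 0.9),
                  c(0.9, 0.8, 0.2), c(0.8, 0.3, 0.8), c(0.2, 0.8, 0.8),
                  c(0.95, 0.6, 0.3), c(0.7, 0.7, 0.7))
    nodes <- vector("list", n)
    for (i in seq_len(n)) {
      dims <- c(28L, 28L, 28L)
      ctr <- (dims - 1) / 2
      g <- voxel_grid(dims)
      ax <- 4.5 + 2.5 * runif(3)  # semi-axes, at most 7 voxels
      blob <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
        ((g$z - ctr[3]) / ax[3])^2 <= 1
      inten <- array(40 + 10 * rnorm(prod(dims)), dims)
      inten[blob] <- 700 + 30 * rnorm(sum(blob))
      pos <- base[i, ] + runif(3, -1.5, 1.5)
      pose <- pose_compose(
        pose_translation(pos),
        pose_rotation("z", runif(1, 0, 360)),
        pose_rotation("x", runif(1, 0, 360)),
        pose_translation(-ctr))
      tf <- tf_preset("bone_binary", color = cols[i, ])
      nodes[[i]] <- volume_node(scalar_volume(inten, name = paste0("blob", i)),
                                tf, pose = pose)
    }
    cam <- camera_look_at(c(52, -42, 34), c(0, 0, 0), vfov = 42,
                          image_size = image_size, near = 1, far = 400)
    list(scene = scene(nodes), camera = cam)
  })
}

#' Two-volume scene with overlapping opaque bars
#'
#' Two homogeneous opaque bars crossing each other in world space, one
#' tilted toward the camera, so each volume is the nearer one on part
#' of the image. Rendering the two volumes independently and
#' alpha-blending the results without depth clamping/testing produces
#' the classic multi-volume occlusion failure; the depth-buffer
#' renderer resolves it.
#'
#' @param seed integer seed for the bar noise.
#' @param image_size camera image size.
#' @return List with `scene` and `camera`.
#' @export
overlapping_bars_scene <- function(seed = 0L, image_size = c(128, 128)) {
  local_seed(seed, {
    dims <- c(48L, 12L, 12L)
    bar <- function(name) {
      inten <- array(700 + 30 * rnorm(prod(dims)), dims)
      scalar_volume(inten, name = name)
    }
    ctr <- (dims - 1) / 2
    pose_a <- pose_translation(-ctr)
    pose_b <- pose_compose(pose_rotation("x", 25),
                           pose_rotation("z", 90),
                           pose_translation(-ctr))
    node_a <- volume_node(bar("bar_x"), tf_preset("bone_binary", color = c(0.2, 0.45, 0.9)),
                          pose = pose_a)
    node_b <- volume_node(bar("bar_y"), tf_preset("bone_binary", color = c(0.95, 0.55, 0.15)),
                          pose = pose_b)
    cam <- camera_look_at(c(0, 0, 110), c(0, 0, 0), up = c(0, 1, 0),
                          vfov = 40, image_size = image_size,
                          near = 1, far = 400)
    list(scene = scene(node_a, node_b), camera = cam)
  })
}
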