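# Volume and image input/output. Volumes round-trip through NIfTI
# (via RNifti) or NRRD (minimal raw-encoding reader/writer); rendered
# images go to PNG (sRGB-encoded color) and PFM (32-bit float depth).
# The voxel-to-world transform is taken as given by the container's
# primary transform field; no reorientation to a canonical axis order
# is performed (bit-exact round trips matter more to a renderer than
# canonical axes). Voxel indices are 0-based in the affine convention,
# matching NIfTI.

#' Read a scalar volume or mask
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and NRRD (`.nrrd`, raw encoding).
#' Spacing is taken from the per-axis voxel size and the rotational/
#' translational part of the voxel-to-world transform is attached as a
#' `pose` attribute (local mm to world mm), which [volume_node()] picks
#' up automatically.
#'
#' @param path input file path.
#' @param as_mask read as a segmentation mask (8-bit labels).
#' @return A [scalar_volume()] (with a `pose` attribute) or a
#'   [segmentation_mask()].
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- volume_format(path)
  parsed <- switch(ext,
    nifti = read_nifti_raw(path),
    nrrd = read_nrrd_raw(path))
  if (as_mask) {
    if (any(parsed$data < 0) || any(parsed$data > 255))
      stop("mask labels out of the 8-bit range [0, 255] in ", path)
    m <- segmentation_mask(array(as.integer(round(parsed$data)),
                                 dim(parsed$data)))
    return(m)
  }
  v <- scalar_volume(parsed$data, spacing = parsed$spacing,
                     name = sub("\\.(nii(\\.gz)?|nrrd)$", "", basename(path)))
  attr(v, "pose") <- parsed$pose
  v
}

#' Write a scalar volume or mask
#'
#' The voxel-to-world affine written to the file is
#' `pose %*% diag(c(spacing, 1))` (voxel index to world mm). Masks are
#' stored as unsigned 8-bit; labels outside `[0, 255]` are an error.
#'
#' @param x a [scalar_volume()] or [segmentation_mask()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param pose optional [affine_pose()] (default: the volume's `pose`
#'   attribute, else identity).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, pose = NULL) {
  is_mask <- inherits(x, "voxray_mask")
  if (!is_mask && !inherits(x, "voxray_volume"))
    stop("`x` must be a scalar_volume or segmentation_mask")
  if (is_mask) {
    if (any(x$labels < 0L) || any(x$labels > 255L))
      stop("mask labels out of the 8-bit range [0, 255]")
    data <- x$labels
    spacing <- c(1, 1, 1)
  } else {
    data <- x$data
    spacing <- x$spacing
  }
  if (is.null(pose)) pose <- attr(x, "pose")
  if (is.null(pose)) pose <- affine_pose()
  affine <- pose$matrix %*% diag(c(spacing, 1))
  ext <- volume_format(path)
  if (ext == "nifti") write_nifti_raw(data, spacing, affine, path, is_mask)
  else write_nrrd_raw(data, affine, path, is_mask)
  invisible(path)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.nrrd$", path)) "nrrd"
  else stop("unknown volume extension: ", basename(path),
            " (expected .nii, .nii.gz or .nrrd)")
}

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  if (length(dim(data)) != 3L) stop("expected a 3D volume in ", path)
  affine <- unclass(RNifti::xform(img))
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("non-positive voxel spacing in ", path)
  pose <- affine_pose(affine %*% diag(c(1 / spacing, 1)))
  list(data = data, spacing = spacing, pose = pose)
}

write_nifti_raw <- function(data, spacing, affine, path, is_mask) {
  storage.mode(data) <- if (is_mask) "integer" else "double"
  img <- RNifti::asNifti(data, datatype = if (is_mask) "uint8" else "double")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
}

# --- NRRD (minimal: 3D, raw encoding, little endian) ------------------

write_nrrd_raw <- function(data, affine, path, is_mask) {
  dims <- dim(data)
  type <- if (is_mask) "uint8" else "double"
  dirs <- apply(affine[1:3, 1:3], 2, function(cc)
    sprintf("(%.17g,%.17g,%.17g)", cc[1], cc[2], cc[3]))
  hdr <- c(
    "NRRD0004",
    "# voxray",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dims, collapse = " ")),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    paste0("space directions: ", paste(dirs, collapse = " ")),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            affine[1, 4], affine[2, 4], affine[3, 4]),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (is_mask) {
    writeBin(as.raw(as.integer(data)), con)
  } else {
    writeBin(as.vector(as.double(data)), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_nrrd_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    hdr <- c(hdr, line)
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path)
  fields <- hdr[grepl(":", hdr, fixed = TRUE) & !grepl("^#", hdr)]
  keys <- trimws(sub(":.*$", "", fields))
  vals <- trimws(sub("^[^:]*:", "", fields))
  getf <- function(k, required = TRUE) {
    i <- match(k, keys)
    if (is.na(i)) {
      if (required) stop("NRRD header missing field '", k, "' in ", path)
      return(NULL)
    }
    vals[i]
  }
  type <- getf("type")
  if (!type %in% c("double", "uint8"))
    stop("unsupported NRRD type '", type, "' in ", path)
  if (getf("encoding") != "raw")
    stop("unsupported NRRD encoding '", getf("encoding"), "' in ", path)
  dims <- as.integer(strsplit(getf("sizes"), "\\s+")[[1]])
  if (length(dims) != 3L) stop("expected 3D sizes in ", path)
  n <- prod(dims)
  data <- if (type == "uint8") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "double", n = n, size = 8, endian = "little")
  }
  if (length(data) != n) stop("truncated NRRD data in ", path)
  data <- array(as.numeric(data), dims)
  parse_triple <- function(s)
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  dirs_str <- regmatches(getf("space directions"),
                         gregexpr("\\([^)]*\\)", getf("space directions")))[[1]]
  lin <- vapply(dirs_str, parse_triple, numeric(3))
  origin <- getf("space origin", required = FALSE)
  origin <- if (is.null(origin)) c(0, 0, 0) else parse_triple(origin)
  affine <- rbind(cbind(lin, origin), c(0, 0, 0, 1))
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  pose <- affine_pose(affine %*% diag(c(1 / spacing, 1)))
  list(data = data, spacing = spacing, pose = pose)
}

# --- rendered-image output -------------------------------------------

srgb_encode <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' Write a render to image files
#'
#' Color goes to an 8-bit PNG (linear RGB encoded to sRGB); depth goes
#' to a 32-bit float grayscale PFM holding ray distances in mm (the far
#' distance where nothing was hit), which stays comparable across
#' resolutions and far planes.
#'
#' @param render a `voxray_render` from [render_scene()] /
#'   [render_onepass()] (or a plain H x W x 3 array for `color_path`).
#' @param color_path output PNG path, or `NULL` to skip.
#' @param depth_path output PFM path, or `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_image <- function(render, color_path = NULL, depth_path = NULL) {
  written <- character()
  if (!is.null(color_path)) {
    img <- if (is.array(render)) render else render$color
    png::writePNG(srgb_encode(img), color_path)
    written <- c(written, color_path)
  }
  if (!is.null(depth_path)) {
    if (is.array(render)) stop("depth output needs a voxray_render")
    write_pfm(render$depth, depth_path)
    written <- c(written, depth_path)
  }
  invisible(written)
}

#' Read a PNG written by [write_image()] back to linear RGB
#'
#' @param path PNG path.
#' @return H x W x 3 linear RGB array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  srgb_decode(img)
}

#' Write / read a grayscale PFM depth image
#'
#' Portable Float Map, 32-bit little-endian floats, rows stored bottom
#' to top as the format requires.
#'
#' @param depth H x W numeric matrix.
#' @param path file path.
#' @return `write_pfm`: `path` invisibly; `read_pfm`: the matrix.
#' @export
write_pfm <- function(depth, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  H <- nrow(depth); W <- ncol(depth)
  writeLines(c("Pf", paste(W, H), "-1.0"), con)
  # bottom row first
  vals <- as.vector(t(depth[H:1, , drop = FALSE]))
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_pfm
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (magic != "Pf") stop("not a grayscale PFM file: ", path)
  sz <- as.integer(strsplit(readLines(con, n = 1L), "\\s+")[[1]])
  scale <- as.numeric(readLines(con, n = 1L))
  W <- sz[1]; H <- sz[2]
  vals <- readBin(con, "double", n = W * H, size = 4,
                  endian = if (scale < 0) "little" else "big")
  m <- matrix(vals, nrow = W, ncol = H)
  t(m)[H:1, , drop = FALSE]
}
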