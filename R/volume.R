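#' Binarized trabecular volume
#'
#' A `binary_volume` is the microstructural ground truth of the pipeline: a 3D
#' logical grid (bone = `TRUE`, marrow = `FALSE`) with an isotropic voxel size
#' in micrometres and a physical origin in millimetres. Meshes live in mm; the
#' voxel size carries the um <-> mm conversion.
#'
#' @param data 3D logical (or 0/1) array, bone = TRUE.
#' @param voxel_size_um isotropic voxel edge length, micrometres (> 0).
#' @param origin_mm physical position of the corner of voxel (1,1,1), mm.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, voxel_size_um, origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("`data` must be a 3D array with all dimensions >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("`data` must not contain NA")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         origin_mm = as.numeric(origin_mm)),
    class = "binary_volume"
  )
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %.1f um, BV/TV = %.4f\n",
              d[1], d[2], d[3], x$voxel_size_um, bvtv(x)))
  invisible(x)
}

#' Bone volume fraction of a volume or sub-window
#'
#' BV/TV is the number of bone voxels divided by the total voxel count. This is
#' the density variable rho of the constitutive power law.
#'
#' @param volume a [binary_volume()].
#' @param lo,hi optional 1-based inclusive voxel index bounds of a sub-window.
#' @return fraction in \[0, 1\].
#' @export
bvtv <- function(volume, lo = NULL, hi = NULL) {
  stopifnot(inherits(volume, "binary_volume"))
  d <- volume$data
  if (!is.null(lo)) {
    dm <- dim(d)
    if (any(lo < 1L) || any(hi > dm) || any(hi < lo))
      stop("window bounds out of range")
    d <- d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  mean(d)
}

#' Periodic rod-lattice volume with controllable anisotropy
#'
#' Generates a union of axis-aligned solid cylinders ("struts") on a periodic
#' lattice, one family per axis, emulating the directed strut architecture of
#' trabecular bone. Thicker struts along an axis yield a larger mean intercept
#' length, hence a dominant fabric eigenvalue, along that axis; equal radii give
#' a cubic (fabric-isotropic) lattice.
#'
#' @param shape integer 3-vector of voxel counts.
#' @param strut_radii_um radii of the x-, y- and z-running struts, um.
#' @param spacing_um lattice period, um (radii must be < spacing/2).
#' @param voxel_size_um voxel edge, um.
#' @return a [binary_volume()].
#' @export
rod_lattice_volume <- function(shape, strut_radii_um, spacing_um,
                               voxel_size_um = 82) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive integers")
  if (length(strut_radii_um) != 3L || any(strut_radii_um <= 0))
    stop("`strut_radii_um` must be 3 positive radii")
  if (any(strut_radii_um >= spacing_um / 2))
    stop("strut radii must be smaller than half the lattice spacing")
  if (any(shape * voxel_size_um < 3 * spacing_um))
    stop("`shape` too small: need at least 3 lattice periods per axis")

  # voxel-centre coordinates and distance to the nearest lattice line
  ax <- lapply(shape, function(n) (seq_len(n) - 0.5) * voxel_size_um)
  dev <- lapply(ax, function(x) x - spacing_um * round(x / spacing_um))
  d1 <- dev[[1]]; d2 <- dev[[2]]; d3 <- dev[[3]]

  vol <- array(FALSE, dim = shape)
  # struts along x: lattice lines in the (y, z) plane
  yz <- outer(d2^2, d3^2, `+`) <= strut_radii_um[1]^2
  vol <- vol | aperm(array(yz, dim = shape[c(2, 3, 1)]), c(3, 1, 2))
  # struts along y: lattice lines in the (x, z) plane
  xz <- outer(d1^2, d3^2, `+`) <= strut_radii_um[2]^2
  vol <- vol | aperm(array(xz, dim = shape[c(1, 3, 2)]), c(1, 3, 2))
  # struts along z: lattice lines in the (x, y) plane
  xy <- outer(d1^2, d2^2, `+`) <= strut_radii_um[3]^2
  vol <- vol | array(xy, dim = shape)

  binary_volume(vol, voxel_size_um)
}

with_local_seed <- function(seed, code) {
  # run `code` under a fixed RNG state without disturbing the caller's stream
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Thresholded Gaussian random field volume
#'
#' Smooths white noise with an anisotropic Gaussian kernel and thresholds it at
#' the quantile matching `target_bvtv`, producing an irregular two-phase
#' microstructure with trabecular-like texture. Longer correlation lengths
#' stretch the solid phase along that axis, so the fabric eigenvectors align
#' with the stretched axes. Deterministic for a given `seed`.
#'
#' @param shape integer 3-vector of voxel counts.
#' @param correlation_lengths_um Gaussian kernel sigma per axis, um.
#' @param target_bvtv desired bone volume fraction, strictly in (0, 1).
#' @param seed integer RNG seed.
#' @param voxel_size_um voxel edge, um.
#' @return a [binary_volume()] whose BV/TV is within 1/n of `target_bvtv`.
#' @export
gaussian_field_volume <- function(shape, correlation_lengths_um, target_bvtv,
                                  seed, voxel_size_um = 82) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop("`shape` must be 3 integers >= 2")
  if (!is.numeric(target_bvtv) || target_bvtv <= 0 || target_bvtv >= 1)
    stop("`target_bvtv` must be strictly between 0 and 1 (all-solid/all-empty targets are unreachable)")
  if (length(correlation_lengths_um) != 3L || any(correlation_lengths_um <= 0))
    stop("`correlation_lengths_um` must be 3 positive lengths")

  n <- prod(shape)
  noise <- with_local_seed(seed, array(stats::rnorm(n), dim = shape))
  sigma_vox <- correlation_lengths_um / voxel_size_um
  smooth <- gaussian_blur3d_cpp(as.numeric(noise), shape, as.numeric(sigma_vox))

  k <- max(1L, min(n - 1L, as.integer(round(target_bvtv * n))))
  # exact voxel count via order statistics (ties broken deterministically)
  bone <- array(rank(-smooth, ties.method = "first") <= k, dim = shape)
  binary_volume(bone, voxel_size_um)
}

#' Write / read a volume as raw uint8 with a JSON sidecar
#'
#' The `.raw` file stores one byte per voxel (1 = bone) in ZYX axis order
#' (z fastest on disk); the `.json` sidecar records shape, voxel size and axis
#' order so the pair is self-describing.
#'
#' @param volume a [binary_volume()].
#' @param path path of the `.raw` file (sidecar gets `.json` appended).
#' @return `path`, invisibly (writer); a [binary_volume()] (reader).
#' @export
write_volume_raw <- function(volume, path) {
  stopifnot(inherits(volume, "binary_volume"))
  zyx <- aperm(volume$data, c(3, 2, 1))
  writeBin(as.raw(as.integer(zyx)), path)
  meta <- list(shape_zyx = dim(zyx), voxel_size_um = volume$voxel_size_um,
               origin_mm = volume$origin_mm, axis_order = "ZYX")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_raw
#' @export
read_volume_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$axis_order, "ZYX")) stop("unsupported axis order: ", meta$axis_order)
  shape_zyx <- as.integer(meta$shape_zyx)
  bytes <- readBin(path, what = "raw", n = prod(shape_zyx))
  if (length(bytes) != prod(shape_zyx)) stop("raw file shorter than sidecar shape implies")
  zyx <- array(as.integer(bytes) > 0L, dim = shape_zyx)
  binary_volume(aperm(zyx, c(3, 2, 1)), meta$voxel_size_um, as.numeric(meta$origin_mm))
}

#' Write / read a volume as a multi-page TIFF stack
#'
#' One 8-bit page per z-slice (bone = 255). Requires the `tiff` package.
#'
#' @param volume a [binary_volume()].
#' @param path `.tif` output path.
#' @param voxel_size_um voxel size to attach on read (TIFF carries no 3D metadata).
#' @return `path`, invisibly (writer); a [binary_volume()] (reader).
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "binary_volume"))
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required for TIFF IO")
  pages <- lapply(seq_len(dim(volume$data)[3]),
                  function(k) volume$data[, , k] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path, voxel_size_um) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required for TIFF IO")
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(FALSE, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] > 0.5
  binary_volume(arr, voxel_size_um)
}
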