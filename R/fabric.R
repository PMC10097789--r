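#' Quasi-uniform unit directions on the upper hemisphere
#'
#' Fibonacci-spiral sampling; antipodal pairs are redundant for MIL, so the
#' hemisphere suffices.
#'
#' @param n number of directions (>= 9 for a fabric fit).
#' @return n x 3 matrix of unit vectors with z >= 0.
#' @export
fibonacci_hemisphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                      # cos(theta) in (0, 1): upper hemisphere
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Mean intercept length over a window
#'
#' For each direction w, parallel test lines spaced `line_spacing_vox` voxels
#' apart are marched through the axis-aligned window; MIL(w) is the total
#' test-line length inside the window divided by the number of bone/marrow
#' transitions crossed (plain total-length / crossings; no bone-fraction
#' normalization). Directions along which no interface is crossed are flagged
#' with `NA`, never reported as infinite. Single-phase windows return a
#' degenerate result consumed by the constitutive threshold rules.
#'
#' @param volume a [binary_volume()].
#' @param window list with 1-based inclusive voxel bounds `lo`, `hi`.
#' @param n_directions number of hemisphere directions (ignored when
#'   `directions` is given).
#' @param line_spacing_vox spacing between parallel test lines, voxels.
#' @param directions optional explicit d x 3 matrix of unit directions.
#' @param step_vox marching step along each line, voxels.
#' @return object of class `mil_samples`: `directions`, `mil_um` (NA where no
#'   crossings), `window_bvtv`, `degenerate`.
#' @export
compute_mil <- function(volume, window, n_directions = 128,
                        line_spacing_vox = 2, directions = NULL,
                        step_vox = 0.5) {
  stopifnot(inherits(volume, "binary_volume"))
  dm <- dim(volume$data)
  lo <- as.integer(window$lo); hi <- as.integer(window$hi)
  if (any(lo < 1L) || any(hi > dm) || any(hi < lo)) stop("window outside the volume")
  wb <- bvtv(volume, lo, hi)
  if (wb == 0 || wb == 1) {
    return(structure(list(directions = NULL, mil_um = NULL,
                          window_bvtv = wb, degenerate = TRUE),
                     class = "mil_samples"))
  }
  if (is.null(directions)) directions <- fibonacci_hemisphere(n_directions)
  directions <- as.matrix(directions)
  vol_int <- attr(volume, "int_cache")
  if (is.null(vol_int)) vol_int <- as.integer(volume$data)
  raw <- mil_sample_cpp(vol_int, dm, lo, hi, directions,
                        line_spacing_vox, step_vox)
  mil <- ifelse(raw[, 2] > 0, raw[, 1] / raw[, 2] * volume$voxel_size_um, NA_real_)
  structure(list(directions = directions, mil_um = mil, window_bvtv = wb,
                 degenerate = FALSE),
            class = "mil_samples")
}

#' Fit the second-order fabric tensor from MIL samples
#'
#' Least-squares fit of the orientation ellipsoid MIL(w)^(-2) = w' H w over the
#' sampled directions (the Harrigan-Mann convention). Under this convention the
#' direction of the largest MIL carries the smallest eigenvalue h of H and thus
#' the largest eigenvalue mu = h^(-1/2) of M = H^(-1/2), i.e. the first fabric
#' eigenvector marks the stiffest direction. Eigenvalues of the fitted H are
#' floored at a small positive fraction of the largest before inversion; an
#' indefinite fit after that projection is an error.
#'
#' @param samples a `mil_samples` object (or a list with `directions` and
#'   `mil_um`).
#' @return object of class `fabric_result`: `H`, `M` (= H^(-1/2)), `mu`
#'   (eigenvalues of M, descending), `m` (normalized, sum = 3), `frame`
#'   (right-handed orthonormal eigenvector triad, columns matching `mu`).
#' @export
fit_fabric <- function(samples) {
  if (isTRUE(samples$degenerate)) stop("degenerate MIL samples: single-phase window")
  ok <- !is.na(samples$mil_um) & samples$mil_um > 0
  w <- samples$directions[ok, , drop = FALSE]
  y <- samples$mil_um[ok]^(-2)
  if (nrow(w) < 9L) stop("need >= 9 valid MIL directions, got ", nrow(w))
  A <- cbind(w[, 1]^2, w[, 2]^2, w[, 3]^2,
             2 * w[, 1] * w[, 2], 2 * w[, 1] * w[, 3], 2 * w[, 2] * w[, 3])
  qrA <- qr(A)
  if (qrA$rank < 6L) stop("MIL directions do not span 3D: 6-parameter fit is singular")
  h <- qr.coef(qrA, y)
  H <- matrix(c(h[1], h[4], h[5],
                h[4], h[2], h[6],
                h[5], h[6], h[3]), 3, 3)
  eg <- eigen(H, symmetric = TRUE)
  floor_ev <- 1e-8 * max(abs(eg$values))
  if (floor_ev <= 0) stop("fabric fit collapsed to zero tensor")
  ev <- pmax(eg$values, floor_ev)
  if (any(ev <= 0))
    stop("indefinite fabric fit after projection; eigenvalues: ",
         paste(signif(eg$values, 4), collapse = ", "))
  H <- eg$vectors %*% diag(ev) %*% t(eg$vectors)
  fabric_from_H(H)
}

#' Build a fabric result from a symmetric positive-definite H tensor
#'
#' Derives M = H^(-1/2), its eigenvalues mu (descending), the normalized
#' eigenvalues m (mean 1, sum 3) and a right-handed eigenvector frame.
#'
#' @param H symmetric positive-definite 3 x 3 matrix.
#' @return a `fabric_result`.
#' @export
fabric_from_H <- function(H) {
  if (max(abs(H - t(H))) > 1e-9 * max(abs(H))) stop("H must be symmetric")
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  if (any(eg$values <= 0))
    stop("H must be positive-definite; eigenvalues: ",
         paste(signif(eg$values, 4), collapse = ", "))
  mu_all <- eg$values^(-0.5)           # h ascending would give mu descending
  ord <- order(mu_all, decreasing = TRUE)
  mu <- mu_all[ord]
  V <- eg$vectors[, ord, drop = FALSE]
  if (det(V) < 0) V[, 3] <- -V[, 3]
  M <- eg$vectors %*% diag(eg$values^(-0.5)) %*% t(eg$vectors)
  m <- 3 * mu / sum(mu)
  structure(list(H = H, M = M, mu = mu, m = m, frame = V),
            class = "fabric_result")
}

#' @export
print.fabric_result <- function(x, ...) {
  cat(sprintf("<fabric_result> m = (%.3f, %.3f, %.3f), m1/m3 = %.3f\n",
              x$m[1], x$m[2], x$m[3], x$m[1] / x$m[3]))
  invisible(x)
}

#' Map BV/TV and fabric onto mesh elements
#'
#' For every solid element, a cubic window of `window_size_mm` centred at the
#' element centroid is carved out of the volume; the window's bone fraction
#' becomes the element density rho and its MIL fit the element fabric.
#' Single-phase windows (or fits with too few valid directions) are flagged
#' degenerate and carry no fabric; the constitutive rules turn them isotropic.
#'
#' @param volume a [binary_volume()].
#' @param mesh a [tet_mesh()] whose solid elements lie inside the volume.
#' @param window_size_mm MIL window edge, mm (default 2.5, matching the mean
#'   element size the mapping is designed around).
#' @param elements element indices to process (default: all).
#' @param n_directions,line_spacing_vox passed to [compute_mil()].
#' @return object of class `element_structure`: a data.frame with `element`,
#'   `rho`, `degenerate`, `m1`, `m2`, `m3`, and frame direction cosines
#'   `f11..f33` (columns of the fabric frame), plus attribute `fabric`
#'   (list of `fabric_result` or NULL).
#' @export
element_structure <- function(volume, mesh, window_size_mm = 2.5,
                              elements = seq_len(nrow(mesh$tets)),
                              n_directions = 128, line_spacing_vox = 2) {
  stopifnot(inherits(volume, "binary_volume"), inherits(mesh, "tet_mesh"))
  vox_mm <- volume$voxel_size_um / 1000
  dm <- dim(volume$data)
  cents <- tet_centroids(mesh)
  half <- window_size_mm / 2
  # one-off integer view of the voxel grid, shared by all per-element MIL calls
  attr(volume, "int_cache") <- as.integer(volume$data)
  fabrics <- vector("list", length(elements))
  rho <- numeric(length(elements)); degen <- logical(length(elements))
  mmat <- matrix(NA_real_, length(elements), 3)
  fmat <- matrix(NA_real_, length(elements), 9)

  for (ii in seq_along(elements)) {
    e <- elements[ii]
    c_mm <- cents[e, ] - volume$origin_mm
    c_vox <- c_mm / vox_mm
    if (any(c_vox < 0) || any(c_vox > dm))
      stop("centroid of element ", e, " lies outside the volume")
    lo <- pmax(1L, as.integer(ceiling(c_vox - half / vox_mm + 0.5)))
    hi <- pmin(dm, as.integer(floor(c_vox + half / vox_mm + 0.5)))
    hi <- pmax(hi, lo)
    rho[ii] <- bvtv(volume, lo, hi)
    if (rho[ii] == 0 || rho[ii] == 1) { degen[ii] <- TRUE; next }
    mil <- compute_mil(volume, list(lo = lo, hi = hi),
                       n_directions = n_directions,
                       line_spacing_vox = line_spacing_vox)
    fab <- tryCatch(fit_fabric(mil), error = function(e) NULL)
    if (is.null(fab)) { degen[ii] <- TRUE; next }
    fabrics[[ii]] <- fab
    mmat[ii, ] <- fab$m
    fmat[ii, ] <- as.vector(fab$frame)
  }

  out <- data.frame(element = elements, rho = rho, degenerate = degen,
                    m1 = mmat[, 1], m2 = mmat[, 2], m3 = mmat[, 3])
  fcols <- as.data.frame(fmat)
  names(fcols) <- paste0("f", rep(1:3, 3), rep(1:3, each = 3))
  out <- cbind(out, fcols)
  attr(out, "fabric") <- fabrics
  class(out) <- c("element_structure", "data.frame")
  out
}

#' Export a per-element structure table as CSV
#'
#' Columns: element id, rho (BV/TV), normalized fabric eigenvalues and the
#' fabric frame as 9 direction cosines.
#'
#' @param structures an [element_structure()] table.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_structure_csv <- function(structures, path) {
  utils::write.csv(as.data.frame(structures), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-element structure table from CSV
#'
#' Inverse of [write_structure_csv()]: rebuilds the `element_structure` table
#' including the per-element fabric list (eigenvalues and frame; the raw H
#' tensor is not stored in the CSV and is reconstructed from them).
#'
#' @param path CSV written by [write_structure_csv()].
#' @return an `element_structure` table.
#' @export
read_structure_csv <- function(path) {
  df <- utils::read.csv(path)
  fabrics <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (isTRUE(df$degenerate[i]) || is.na(df$m1[i])) next
    m <- c(df$m1[i], df$m2[i], df$m3[i])
    V <- matrix(as.numeric(df[i, paste0("f", rep(1:3, 3), rep(1:3, each = 3))]), 3, 3)
    mu <- m          # same ordering; only ratios and the frame are consumed downstream
    H <- V %*% diag(mu^-2) %*% t(V)
    fabrics[[i]] <- structure(list(H = H, M = V %*% diag(mu) %*% t(V),
                                   mu = mu, m = m, frame = V),
                              class = "fabric_result")
  }
  attr(df, "fabric") <- fabrics
  class(df) <- c("element_structure", "data.frame")
  df
}
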