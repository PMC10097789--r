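# Shared fixtures, built lazily once per test run (they are the slow part:
# meshing, volume synthesis and per-element MIL mapping).
.fx <- new.env(parent = emptyenv())

# small surrogate femur used by fem / pipeline tests
fx_mesh <- function() {
  if (is.null(.fx$mesh)) .fx$mesh <- femur_like_mesh(14, 3.2)
  .fx$mesh
}

# seeded volume sized to wrap a mesh (plus MIL window margin), origin aligned
fx_volume_for <- function(mesh, voxel_um = 300, seed = 2, target_bvtv = 0.3,
                          corr_um = c(600, 1200, 600), margin_mm = 1.5) {
  lo <- apply(mesh$nodes, 2, min) - margin_mm
  hi <- apply(mesh$nodes, 2, max) + margin_mm
  shape <- as.integer(ceiling((hi - lo) / (voxel_um / 1000)))
  v <- gaussian_field_volume(shape, corr_um, target_bvtv, seed = seed,
                             voxel_size_um = voxel_um)
  v$origin_mm <- lo
  v
}

fx_structures <- function() {
  if (is.null(.fx$structures)) {
    mesh <- fx_mesh()
    vol <- fx_volume_for(mesh)
    solid <- setdiff(seq_len(nrow(mesh$tets)), mesh$element_sets$tendon_cartilage)
    .fx$structures <- element_structure(vol, mesh, window_size_mm = 2.5,
                                        elements = solid, n_directions = 48)
  }
  .fx$structures
}

# synthetic element_structure with uniform density and isotropic fabric,
# for tests that need materials without the MIL stage
uniform_structures <- function(mesh, rho = 0.3, m = c(1, 1, 1),
                               frame = diag(3)) {
  solid <- setdiff(seq_len(nrow(mesh$tets)), mesh$element_sets$tendon_cartilage)
  n <- length(solid)
  df <- data.frame(element = solid, rho = rho, degenerate = FALSE,
                   m1 = m[1], m2 = m[2], m3 = m[3])
  fcols <- as.data.frame(matrix(rep(as.vector(frame), each = n), n, 9))
  names(fcols) <- paste0("f", rep(1:3, 3), rep(1:3, each = 3))
  df <- cbind(df, fcols)
  fab <- structure(list(H = frame %*% diag(m^-2) %*% t(frame),
                        M = frame %*% diag(m) %*% t(frame),
                        mu = m, m = m, frame = frame),
                   class = "fabric_result")
  attr(df, "fabric") <- rep(list(fab), n)
  class(df) <- c("element_structure", "data.frame")
  df
}

# brute-force axis-aligned MIL oracle: one test line per voxel row, exact
# transition count (no marching, no spacing) -- the reference the sampled
# MIL implementation must approximate
mil_axis_oracle <- function(volume, axis) {
  a <- volume$data * 1L
  perm <- switch(axis, x = c(1, 2, 3), y = c(2, 1, 3), z = c(3, 1, 2))
  a <- aperm(a, perm)
  d <- dim(a)
  flat <- matrix(a, nrow = d[1])
  crossings <- sum(abs(diff(flat)))
  total_len_vox <- prod(d)
  total_len_vox / crossings * volume$voxel_size_um
}

# direct fourth-order stiffness rotation (oracle for the 6x6 Bond transform)
rotate_stiffness_oracle <- function(C_voigt, Q) {
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(3, 1), c(1, 2))
  vid <- matrix(0L, 3, 3)
  for (a in 1:6) { vid[idx[a, 1], idx[a, 2]] <- a; vid[idx[a, 2], idx[a, 1]] <- a }
  C4 <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    C4[i, j, k, l] <- C_voigt[vid[i, j], vid[k, l]]
  C4r <- array(0, c(3, 3, 3, 3))
  for (p in 1:3) for (q in 1:3) for (r in 1:3) for (s in 1:3) {
    acc <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      acc <- acc + Q[p, i] * Q[q, j] * Q[r, k] * Q[s, l] * C4[i, j, k, l]
    C4r[p, q, r, s] <- acc
  }
  out <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6)
    out[a, b] <- C4r[idx[a, 1], idx[a, 2], idx[b, 1], idx[b, 2]]
  out
}

# proper rotation from an axis-angle
rotation_matrix <- function(axis, angle) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# 3-vector cross product for surface-triangle areas in the bar tests
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
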