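#' Tetrahedral mesh
#'
#' Minimal container for linear (4-node, constant-strain) tetrahedral meshes:
#' node coordinates in mm, 1-based connectivity, and named node / element sets.
#' The local node ordering convention is such that the signed volume
#' det(\[x2-x1, x3-x1, x4-x1\])/6 is positive for every element.
#'
#' @param nodes n x 3 numeric matrix, mm.
#' @param tets m x 4 integer matrix, 1-based node indices.
#' @param node_sets named list of integer vectors.
#' @param element_sets named list of integer vectors.
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, node_sets = list(), element_sets = list()) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("`nodes` must be n x 3")
  if (ncol(tets) != 4L) stop("`tets` must be m x 4")
  if (any(tets < 1L) || any(tets > nrow(nodes))) stop("tet node indices out of range")
  for (s in node_sets) if (any(s < 1L | s > nrow(nodes))) stop("node set index out of range")
  for (s in element_sets) if (any(s < 1L | s > nrow(tets))) stop("element set index out of range")
  v <- tet_volumes(nodes, tets)
  if (any(v <= 0))
    stop("inverted or degenerate tets (non-positive volume): elements ",
         paste(utils::head(which(v <= 0), 5L), collapse = ", "))
  structure(list(nodes = nodes, tets = tets, node_sets = node_sets,
                 element_sets = element_sets),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d C3D4 elements, node sets: %s; element sets: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(names(x$node_sets), collapse = ", "),
              paste(names(x$element_sets), collapse = ", ")))
  invisible(x)
}

#' Signed volumes of all tets (mm^3)
#' @param nodes n x 3 coordinates, mm.
#' @param tets m x 4 connectivity.
#' @return numeric vector of signed volumes.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Element centroids (mm)
#' @param mesh a [tet_mesh()].
#' @return m x 3 matrix.
#' @export
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
   mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
}

# Kuhn subdivision of one hexahedron (vertex ids v[1..8] ordered
# (x,y,z) binary: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0) 5:(0,0,1) ...)
# into 6 tets sharing the main diagonal v1-v8; conforming across cells.
.kuhn <- rbind(
  c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8)
)

hex_grid_tets <- function(xs, ys, zs, keep_cell = NULL) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  cells <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L), k = seq_len(nz - 1L))
  if (!is.null(keep_cell)) {
    cx <- (xs[cells$i] + xs[cells$i + 1L]) / 2
    cy <- (ys[cells$j] + ys[cells$j + 1L]) / 2
    cz <- (zs[cells$k] + zs[cells$k + 1L]) / 2
    cells <- cells[keep_cell(cbind(cx, cy, cz)), , drop = FALSE]
  }
  if (nrow(cells) == 0L) stop("meshing failure: no cells inside the solid")
  v <- cbind(nid(cells$i,      cells$j,      cells$k),
             nid(cells$i + 1L, cells$j,      cells$k),
             nid(cells$i,      cells$j + 1L, cells$k),
             nid(cells$i + 1L, cells$j + 1L, cells$k),
             nid(cells$i,      cells$j,      cells$k + 1L),
             nid(cells$i + 1L, cells$j,      cells$k + 1L),
             nid(cells$i,      cells$j + 1L, cells$k + 1L),
             nid(cells$i + 1L, cells$j + 1L, cells$k + 1L))
  tets <- matrix(0L, nrow(v) * 6L, 4L)
  for (t in 1:6) tets[seq(t, by = 6L, length.out = nrow(v)), ] <- v[, .kuhn[t, ]]
  # drop unused nodes, remap
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  nodes <- nodes[used, , drop = FALSE]
  # enforce positive orientation
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  list(nodes = nodes, tets = tets)
}

#' Structured tetrahedral box mesh
#'
#' Meshes an axis-aligned box with a structured grid, splitting every
#' hexahedral cell into 6 tetrahedra (Kuhn subdivision along the main diagonal,
#' conforming across cells). Face node sets `xmin`, `xmax`, ..., `zmax` are
#' created automatically.
#'
#' @param extent_mm positive 3-vector: box size, mm.
#' @param target_edge_mm requested cell edge, mm (actual edge <= target).
#' @return a [tet_mesh()].
#' @export
box_mesh <- function(extent_mm, target_edge_mm) {
  if (any(extent_mm <= 0)) stop("`extent_mm` must be positive")
  if (target_edge_mm > min(extent_mm)) stop("`target_edge_mm` larger than the smallest extent")
  ndiv <- pmax(1L, ceiling(extent_mm / target_edge_mm))
  xs <- seq(0, extent_mm[1], length.out = ndiv[1] + 1L)
  ys <- seq(0, extent_mm[2], length.out = ndiv[2] + 1L)
  zs <- seq(0, extent_mm[3], length.out = ndiv[3] + 1L)
  g <- hex_grid_tets(xs, ys, zs)
  tol <- 1e-9 * max(extent_mm)
  ns <- list(
    xmin = which(abs(g$nodes[, 1]) < tol),
    xmax = which(abs(g$nodes[, 1] - extent_mm[1]) < tol),
    ymin = which(abs(g$nodes[, 2]) < tol),
    ymax = which(abs(g$nodes[, 2] - extent_mm[2]) < tol),
    zmin = which(abs(g$nodes[, 3]) < tol),
    zmax = which(abs(g$nodes[, 3] - extent_mm[3]) < tol)
  )
  tet_mesh(g$nodes, g$tets, node_sets = ns,
           element_sets = list(bone = seq_len(nrow(g$tets))))
}

#' Boundary (surface) triangles and nodes of a tet mesh
#'
#' A face is on the boundary when it belongs to exactly one tet.
#'
#' @param mesh a [tet_mesh()].
#' @return list with `faces` (f x 3 node indices) and `nodes` (unique indices).
#' @export
surface_faces <- function(mesh) {
  tt <- mesh$tets
  faces <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)], tt[, c(1, 3, 4)], tt[, c(2, 3, 4)])
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  bnd <- faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
  list(faces = bnd, nodes = sort(unique(as.vector(bnd))))
}

# anatomically-inspired anchor directions for the 15 muscle attachment patches
# of the bundled load tables, placed on the trochanteric / upper-shaft region
# of the surrogate. Rows: unit-ish direction in (x, y, z) and a height factor
# along the shaft. Invented surrogate positions; only topology matters.
.muscle_anchors <- function(scale) {
  s <- scale
  shaft_z <- 0.55 * s
  rbind(
    Glut_max1 = c(-0.3 * s, -0.55 * s, shaft_z + 0.35 * s),
    Glut_max2 = c(-0.3 * s, -0.75 * s, shaft_z + 0.35 * s),
    Glut_max3 = c(-0.3 * s, -0.95 * s, shaft_z + 0.30 * s),
    Glut_med1 = c( 0.0 * s, -0.30 * s, shaft_z + 0.40 * s),
    Glut_med2 = c( 0.15 * s, -0.35 * s, shaft_z + 0.38 * s),
    Glut_med3 = c(-0.15 * s, -0.35 * s, shaft_z + 0.38 * s),
    Glut_min1 = c( 0.0 * s, -0.45 * s, shaft_z + 0.40 * s),
    Glut_min2 = c( 0.15 * s, -0.50 * s, shaft_z + 0.36 * s),
    Glut_min3 = c(-0.15 * s, -0.50 * s, shaft_z + 0.36 * s),
    Iliacus   = c( 0.25 * s, -0.70 * s, shaft_z - 0.30 * s),
    Pect      = c( 0.20 * s, -0.85 * s, shaft_z - 0.25 * s),
    Perif     = c(-0.25 * s, -0.40 * s, shaft_z + 0.25 * s),
    Psoas     = c( 0.25 * s, -0.78 * s, shaft_z - 0.30 * s),
    Quadfem   = c(-0.25 * s, -0.65 * s, shaft_z + 0.25 * s),
    Gem       = c(-0.25 * s, -0.55 * s, shaft_z + 0.30 * s)
  )
}

#' Surrogate proximal-femur mesh
#'
#' A deliberately simple parametric stand-in for a proximal femur: spherical
#' head centred at the origin, an angled neck capsule, a shaft capsule running
#' distally, and a trochanteric bulge, voxel-meshed on a structured grid and
#' split into tets. The coordinate frame follows the musculoskeletal-model
#' convention used by the bundled load tables: head centre at the origin,
#' +y proximal (up the shaft), +z lateral. Node sets created: `distal_fixed`
#' (distal shaft cross-section), `joint_surface` (upper head cap), and one
#' attachment set per muscle of the bundled tables. Element sets: `bone` and a
#' one-element-thick `tendon_cartilage` layer at the attachments.
#'
#' @param scale_mm head diameter, mm (default 25 gives a ~5000-element mesh
#'   at the default edge length).
#' @param target_edge_mm structured-grid cell edge, mm.
#' @return a [tet_mesh()] with attribute `head_radius_mm`.
#' @export
femur_like_mesh <- function(scale_mm = 25, target_edge_mm = 2.5) {
  if (scale_mm <= 0) stop("`scale_mm` must be positive")
  s <- scale_mm
  r_head <- 0.5 * s
  neck_a <- c(0, 0, 0); neck_b <- c(0, -0.45 * s, 0.55 * s); r_neck <- 0.30 * s
  shaft_a <- neck_b;    shaft_b <- c(0, -2.2 * s, 0.55 * s); r_shaft <- 0.36 * s
  troch_c <- c(0, -0.35 * s, 0.80 * s); r_troch <- 0.30 * s

  dist_capsule <- function(p, a, b, r) {
    ab <- b - a
    ap <- sweep(p, 2L, a)
    t <- pmin(1, pmax(0, (ap %*% ab) / sum(ab^2)))
    q <- sweep(t %*% t(ab), 2L, a, `+`)
    sqrt(rowSums((p - q)^2)) - r
  }
  inside <- function(p) {
    d <- sqrt(rowSums(p^2)) - r_head
    d <- pmin(d, dist_capsule(p, neck_a, neck_b, r_neck))
    d <- pmin(d, dist_capsule(p, shaft_a, shaft_b, r_shaft))
    d <- pmin(d, sqrt(rowSums(sweep(p, 2L, troch_c)^2)) - r_troch)
    d <= 0
  }

  lo <- c(-r_head - 1, shaft_b[2] - r_shaft - 1, -r_head - 1)
  hi <- c(r_head + 1, r_head + 1, troch_c[3] + r_troch + 1)
  mk <- function(a, b) seq(a, b, by = target_edge_mm)
  xs <- mk(lo[1], hi[1]); ys <- mk(lo[2], hi[2]); zs <- mk(lo[3], hi[3])
  g <- tryCatch(hex_grid_tets(xs, ys, zs, keep_cell = inside),
                error = function(e) stop("meshing failure: ", conditionMessage(e)))

  mesh0 <- tet_mesh(g$nodes, g$tets)
  surf <- surface_faces(mesh0)
  snodes <- surf$nodes
  sc <- g$nodes[snodes, , drop = FALSE]

  ymin <- min(g$nodes[, 2])
  distal_fixed <- which(g$nodes[, 2] < ymin + 0.51 * target_edge_mm)

  rad <- sqrt(rowSums(sc^2))
  joint_surface <- snodes[rad <= r_head + 0.75 * target_edge_mm & sc[, 2] > 0.25 * r_head]
  if (length(joint_surface) == 0L) stop("meshing failure: empty joint surface cap")

  anchors <- .muscle_anchors(s)
  node_sets <- list(distal_fixed = distal_fixed, joint_surface = joint_surface)
  k_attach <- 6L
  for (mname in rownames(anchors)) {
    d2 <- rowSums(sweep(sc, 2L, anchors[mname, ])^2)
    node_sets[[mname]] <- snodes[order(d2)[seq_len(min(k_attach, length(snodes)))]]
  }

  attach_nodes <- unique(unlist(node_sets[rownames(anchors)]))
  touches <- matrix(mesh0$tets %in% attach_nodes, ncol = 4L)
  tendon <- which(rowSums(touches) > 0L)
  element_sets <- list(bone = setdiff(seq_len(nrow(g$tets)), tendon),
                       tendon_cartilage = tendon)

  out <- tet_mesh(g$nodes, g$tets, node_sets = node_sets, element_sets = element_sets)
  attr(out, "head_radius_mm") <- r_head
  attr(out, "target_edge_mm") <- target_edge_mm
  out
}
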