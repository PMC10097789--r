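#' Stiffness of one constant-strain tetrahedron
#'
#' Ke = V * B' C B with the constant B-operator of the linear tet. Nodes in mm
#' and C in MPa give Ke in N/mm.
#'
#' @param coords 4 x 3 node coordinates, mm (positive orientation).
#' @param C 6 x 6 stiffness, MPa, Voigt order (11, 22, 33, 23, 31, 12),
#'   engineering shear.
#' @return list: `Ke` (12 x 12, N/mm), `B` (6 x 12, 1/mm), `V` (mm^3).
#' @export
element_stiffness <- function(coords, C) {
  A <- cbind(1, coords)
  detA <- det(A)
  V <- detA / 6
  if (!is.finite(V) || V <= 0)
    stop("inverted or degenerate tet (signed volume ", signif(V, 4), ")")
  G <- solve(A)[2:4, , drop = FALSE]   # G[, a] = grad N_a
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    gx <- G[1, a]; gy <- G[2, a]; gz <- G[3, a]
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- gx
    B[2, c0 + 2] <- gy
    B[3, c0 + 3] <- gz
    B[4, c0 + 2] <- gz; B[4, c0 + 3] <- gy
    B[5, c0 + 1] <- gz; B[5, c0 + 3] <- gx
    B[6, c0 + 1] <- gy; B[6, c0 + 2] <- gx
  }
  Ke <- V * t(B) %*% C %*% B
  list(Ke = (Ke + t(Ke)) / 2, B = B, V = V)
}

#' Assemble the global linear-elastic system
#'
#' Sparse symmetric stiffness over all tets plus, optionally, a star of
#' two-node axial rods from an auxiliary joint-centre node to every node of the
#' joint-surface set. The rods distribute a point reaction applied at the
#' centre node onto the articular surface; their default axial stiffness is
#' 10^3 times a stiff-bone axial estimate, deep in the saturation regime where
#' the bone solution no longer depends on it.
#'
#' @param mesh a [tet_mesh()].
#' @param materials an [assign_materials()] result.
#' @param rods `NULL`, or a list with `joint_center_mm` (3-vector),
#'   `surface_set` (node set name) and optional `stiffness_N_mm`.
#' @return object of class `fe_system`: `K` (sparse, N/mm), `ndof`,
#'   `n_nodes` (mesh nodes, excluding the centre node), `center_node`
#'   (index or NA), `Bs` (list of element B-operators), `Vs` (element volumes),
#'   `mesh`, `materials`.
#' @export
assemble_system <- function(mesh, materials, rods = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n_nodes <- nrow(mesh$nodes)
  m_elem <- nrow(mesh$tets)
  ntrip <- 144L * m_elem
  ii <- integer(ntrip); jj <- integer(ntrip); xx <- numeric(ntrip)
  Bs <- vector("list", m_elem); Vs <- numeric(m_elem)
  pos <- 0L
  for (e in seq_len(m_elem)) {
    es <- element_stiffness(mesh$nodes[mesh$tets[e, ], , drop = FALSE],
                            materials$C[, , e])
    Bs[[e]] <- es$B; Vs[e] <- es$V
    dofs <- as.vector(t(outer(mesh$tets[e, ], 1:3, function(n, d) 3L * (n - 1L) + d)))
    idx <- pos + seq_len(144L)
    ii[idx] <- rep(dofs, times = 12L)
    jj[idx] <- rep(dofs, each = 12L)
    xx[idx] <- as.vector(es$Ke)
    pos <- pos + 144L
  }

  center_node <- NA_integer_
  ndof <- 3L * n_nodes
  if (!is.null(rods)) {
    sset <- mesh$node_sets[[rods$surface_set]]
    if (is.null(sset) || length(sset) == 0L)
      stop("rod surface set '", rods$surface_set, "' is missing or empty")
    center_node <- n_nodes + 1L
    ndof <- 3L * center_node
    kc <- rods$stiffness_N_mm
    if (is.null(kc)) {
      # 10^3 x the stiffest element's axial stiffness E*A/L ~ E*edge
      # (rigid-spreader saturation regime)
      Emax <- materials$E_max
      if (is.null(Emax) || !is.finite(Emax) || Emax <= 0)
        Emax <- max(vapply(seq_len(m_elem), function(e) max(diag(materials$C[, , e])[1:3]),
                           numeric(1)))
      edge <- attr(mesh, "target_edge_mm")
      if (is.null(edge)) edge <- mean(Vs)^(1 / 3)
      kc <- 1e3 * Emax * edge
    }
    cpos <- rods$joint_center_mm
    extra_i <- integer(0); extra_j <- integer(0); extra_x <- numeric(0)
    rod_dirs <- matrix(0, length(sset), 3)
    for (si in seq_along(sset)) {
      s <- sset[si]
      d <- mesh$nodes[s, ] - cpos
      L <- sqrt(sum(d^2))
      if (L <= 1e-12) stop("zero-length rod to node ", s)
      n <- d / L
      rod_dirs[si, ] <- n
      kb <- kc * (n %o% n)
      dofs <- c(3L * (s - 1L) + 1:3, 3L * (center_node - 1L) + 1:3)
      kfull <- rbind(cbind(kb, -kb), cbind(-kb, kb))
      extra_i <- c(extra_i, rep(dofs, times = 6L))
      extra_j <- c(extra_j, rep(dofs, each = 6L))
      extra_x <- c(extra_x, as.vector(kfull))
    }
  }

  Kb <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  Kb <- Matrix::forceSymmetric((Kb + Matrix::t(Kb)) / 2)
  if (is.null(rods)) {
    K <- Kb
    rod_info <- NULL
  } else {
    Kr <- Matrix::sparseMatrix(i = extra_i, j = extra_j, x = extra_x,
                               dims = c(ndof, ndof))
    K <- Matrix::forceSymmetric(Kb + (Kr + Matrix::t(Kr)) / 2)
    rod_info <- list(nodes = sset, dirs = rod_dirs, kc = kc,
                     center_node = center_node)
  }
  structure(list(K = K, K_bone = Kb, ndof = ndof, n_nodes = n_nodes,
                 center_node = center_node, Bs = Bs, Vs = Vs,
                 mesh = mesh, materials = materials,
                 rod_stiffness = if (is.null(rods)) NA_real_ else kc,
                 rods = rod_info),
            class = "fe_system")
}

#' Nodal load vector from a load case
#'
#' Every muscle force (unit direction x magnitude) is split equally over the
#' nodes of its attachment set; the joint reaction is applied at the rod centre
#' node when the system has one, otherwise split over the joint-surface set.
#' The assembled vector sums exactly to the total applied load.
#'
#' @param system an [assemble_system()] result.
#' @param loads a [load_case()] (or `NULL` for a zero vector).
#' @return numeric load vector, N, of length `system$ndof`.
#' @export
apply_loads <- function(system, loads) {
  f <- numeric(system$ndof)
  if (is.null(loads)) return(f)
  mesh <- system$mesh
  for (r in seq_len(nrow(loads$muscles))) {
    row <- loads$muscles[r, ]
    set <- mesh$node_sets[[row$muscle]]
    if (is.null(set) || length(set) == 0L)
      stop("attachment node set missing or empty: ", row$muscle)
    fv <- c(row$nx, row$ny, row$nz) * row$magnitude_N / length(set)
    for (d in 1:3) f[3L * (set - 1L) + d] <- f[3L * (set - 1L) + d] + fv[d]
  }
  rvec <- loads$reaction$direction * loads$reaction$magnitude_N
  if (!is.na(system$center_node)) {
    f[3L * (system$center_node - 1L) + 1:3] <- f[3L * (system$center_node - 1L) + 1:3] + rvec
  } else {
    set <- mesh$node_sets[[loads$distribution$surface_set]]
    if (is.null(set) || length(set) == 0L)
      stop("joint surface set missing for reaction load")
    for (d in 1:3) f[3L * (set - 1L) + d] <- f[3L * (set - 1L) + d] + rvec[d] / length(set)
  }
  f
}

#' Solve the constrained static problem
#'
#' Direct sparse symmetric solve after eliminating fixed dofs (optionally with
#' prescribed non-zero values). Strains and stresses are recovered per element
#' (constant within each linear tet).
#'
#' @param system an [assemble_system()] result.
#' @param f load vector, N.
#' @param fixed_nodes node indices to clamp (all 3 dofs each).
#' @param fixed_values optional k x 3 matrix of prescribed displacements, mm
#'   (default zero).
#' @param fixed_dofs optional explicit dof indices (overrides `fixed_nodes`).
#' @param fixed_dof_values values for `fixed_dofs`.
#' @return object of class `field_result`: `u` (node x 3, mm; includes the rod
#'   centre node as the last row if present), `strain` (m x 6 Voigt,
#'   engineering shear), `stress` (m x 6, MPa), `residual` (relative),
#'   `reactions` (force at fixed dofs, N).
#' @export
solve_static <- function(system, f, fixed_nodes = NULL, fixed_values = NULL,
                         fixed_dofs = NULL, fixed_dof_values = NULL) {
  K <- system$K
  ndof <- system$ndof
  if (is.null(fixed_dofs)) {
    if (is.null(fixed_nodes) || length(fixed_nodes) == 0L)
      stop("under-constrained system: no fixed dofs")
    fixed_dofs <- as.vector(t(outer(fixed_nodes, 1:3, function(n, d) 3L * (n - 1L) + d)))
    if (is.null(fixed_values)) fixed_values <- matrix(0, length(fixed_nodes), 3)
    fixed_dof_values <- as.vector(t(fixed_values))
  } else if (is.null(fixed_dof_values)) {
    fixed_dof_values <- numeric(length(fixed_dofs))
  }
  free <- setdiff(seq_len(ndof), fixed_dofs)
  uc <- fixed_dof_values

  # K %*% u with the rod terms evaluated in difference form: the rods are
  # ~10^3 stiffer than bone, so kc*u_c - kc*u_s through the assembled matrix
  # cancels catastrophically, while kc * n (n . (u_c - u_s)) does not
  rods <- system$rods
  Kb <- if (is.null(system$K_bone)) system$K else system$K_bone
  Kg <- as(as(Kb, "generalMatrix"), "CsparseMatrix")
  kmul <- function(u) {
    y <- spmv_longdouble_cpp(Kg@p, Kg@i, Kg@x, u, ndof)
    if (!is.null(rods)) {
      cdofs <- 3L * (rods$center_node - 1L) + 1:3
      ucen <- u[cdofs]
      for (si in seq_along(rods$nodes)) {
        sdofs <- 3L * (rods$nodes[si] - 1L) + 1:3
        n <- rods$dirs[si, ]
        fax <- rods$kc * sum(n * (ucen - u[sdofs])) * n
        y[sdofs] <- y[sdofs] - fax
        y[cdofs] <- y[cdofs] + fax
      }
    }
    y
  }

  rhs <- f[free] - as.vector(K[free, fixed_dofs, drop = FALSE] %*% uc)
  Kff <- K[free, free]
  # symmetric Jacobi scaling tames the wide stiffness contrasts (rods vs the
  # soft tendon layer) before factorization, and iterative refinement mops up
  d <- sqrt(Matrix::diag(Kff))
  if (any(d <= 0)) stop("singular constrained system: zero diagonal stiffness")
  Dinv <- Matrix::Diagonal(x = 1 / d)
  Ks <- Matrix::forceSymmetric(Dinv %*% Kff %*% Dinv)
  ys <- tryCatch(as.vector(Matrix::solve(Ks, rhs / d)),
                 error = function(e) stop("singular constrained system (under-constrained mesh?): ",
                                          conditionMessage(e)))
  uf <- ys / d
  rhsn <- max(sqrt(sum(rhs^2)), 1e-300)
  u <- numeric(ndof)
  u[fixed_dofs] <- uc
  best_uf <- uf
  relres <- Inf
  stall <- 0L
  for (it in 1:10) {
    u[free] <- uf
    res <- f[free] - kmul(u)[free]
    rr <- sqrt(sum(res^2)) / rhsn
    if (rr < relres) { relres <- rr; best_uf <- uf; stall <- 0L }
    else stall <- stall + 1L
    if (rr <= 1e-13 || stall >= 3L) break
    uf <- uf + as.vector(Matrix::solve(Ks, res / d)) / d
  }
  uf <- best_uf
  if (relres > 1e-8) warning("solver residual ", signif(relres, 3), " exceeds 1e-8")
  u[free] <- uf
  reactions <- kmul(u)[fixed_dofs] - f[fixed_dofs]

  m_elem <- nrow(system$mesh$tets)
  strain <- matrix(0, m_elem, 6)
  stress <- matrix(0, m_elem, 6)
  for (e in seq_len(m_elem)) {
    dofs <- as.vector(t(outer(system$mesh$tets[e, ], 1:3, function(n, d) 3L * (n - 1L) + d)))
    eps <- as.vector(system$Bs[[e]] %*% u[dofs])
    strain[e, ] <- eps
    stress[e, ] <- as.vector(system$materials$C[, , e] %*% eps)
  }
  structure(list(u = matrix(u, ncol = 3, byrow = TRUE), strain = strain,
                 stress = stress, residual = relres, reactions = reactions,
                 fixed_dofs = fixed_dofs, f = f),
            class = "field_result")
}

#' One-call static solve of a loaded mesh
#'
#' Assembles materials and rods, applies a load case, clamps the `fixed_set`
#' node set and solves.
#'
#' @param mesh a [tet_mesh()].
#' @param materials an [assign_materials()] result.
#' @param loads a [load_case()].
#' @param fixed_set name of the clamped node set (default `"distal_fixed"`).
#' @param rod_stiffness_N_mm optional rod stiffness override.
#' @return a `field_result` (see [solve_static()]).
#' @export
fem_solve <- function(mesh, materials, loads, fixed_set = "distal_fixed",
                      rod_stiffness_N_mm = NULL) {
  rods <- c(loads$distribution, list(stiffness_N_mm = rod_stiffness_N_mm))
  system <- assemble_system(mesh, materials, rods = rods)
  f <- apply_loads(system, loads)
  fixed <- mesh$node_sets[[fixed_set]]
  if (is.null(fixed) || length(fixed) == 0L) stop("fixed node set missing or empty: ", fixed_set)
  solve_static(system, f, fixed_nodes = fixed)
}
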