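#' Orthotropic engineering constants from density and fabric
#'
#' The trabecular power law: `E_i = E0 * rho^k * (m_i^2)^l`,
#' `nu_ij = nu0 * (m_i / m_j)^l` and `G_ij = G0 * rho^k * (m_i m_j)^l`, with
#' rho = BV/TV and m the normalized fabric eigenvalues (sum 3). At
#' m = (1, 1, 1) the law reduces to isotropy with E = E0 * rho^k and nu = nu0.
#'
#' @param card a [material_card()].
#' @param rho bone volume fraction, (0, 1].
#' @param m normalized fabric eigenvalues, length 3, positive.
#' @return object of class `engineering_constants`: `E` (E1, E2, E3, MPa),
#'   `nu` (3 x 3, entries nu_ij for i != j), `G` (G23, G31, G12, MPa).
#' @export
engineering_constants <- function(card, rho, m = c(1, 1, 1)) {
  stopifnot(inherits(card, "material_card"))
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    stop("`rho` must be a single value in (0, 1]")
  if (length(m) != 3L || any(m <= 0)) stop("`m` must be 3 positive eigenvalues")
  if (abs(sum(m) - 3) > 1e-6) stop("normalized fabric eigenvalues must sum to 3")
  E <- card$E0 * rho^card$k * (m^2)^card$l
  nu <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) if (i != j) nu[i, j] <- card$nu0 * (m[i] / m[j])^card$l
  G <- card$G0 * rho^card$k *
    c(m[2] * m[3], m[3] * m[1], m[1] * m[2])^card$l
  names(G) <- c("G23", "G31", "G12")
  structure(list(E = E, nu = nu, G = G), class = "engineering_constants")
}

#' Orthotropic compliance matrix (Voigt)
#'
#' Voigt order is fixed package-wide as (11, 22, 33, 23, 31, 12) with
#' engineering shear strains (gamma = 2*eps). The normal block carries
#' -nu_ji/E_j off the diagonal; symmetry (nu_ij/E_i = nu_ji/E_j) is checked and
#' asymmetry beyond tolerance signals inconsistent constants.
#'
#' @param ec an [engineering_constants()] object.
#' @return symmetric 6 x 6 compliance, MPa^-1.
#' @export
compliance_matrix <- function(ec) {
  stopifnot(inherits(ec, "engineering_constants"))
  if (any(ec$E <= 0) || any(ec$G <= 0)) stop("non-positive moduli")
  E <- ec$E; nu <- ec$nu; G <- ec$G
  S <- matrix(0, 6, 6)
  for (i in 1:3) S[i, i] <- 1 / E[i]
  S[1, 2] <- -nu[2, 1] / E[2]; S[2, 1] <- -nu[1, 2] / E[1]
  S[1, 3] <- -nu[3, 1] / E[3]; S[3, 1] <- -nu[1, 3] / E[1]
  S[2, 3] <- -nu[3, 2] / E[3]; S[3, 2] <- -nu[2, 3] / E[2]
  S[4, 4] <- 1 / G[1]; S[5, 5] <- 1 / G[2]; S[6, 6] <- 1 / G[3]
  asym <- max(abs(S - t(S))) / max(abs(S))
  if (asym > 1e-8)
    stop("compliance asymmetry ", signif(asym, 3),
         ": engineering constants violate nu_ij/E_i = nu_ji/E_j")
  (S + t(S)) / 2
}

#' Stiffness matrix from engineering constants
#'
#' @param ec an [engineering_constants()] object.
#' @return symmetric 6 x 6 stiffness, MPa.
#' @export
stiffness_matrix <- function(ec) {
  C <- solve(compliance_matrix(ec))
  (C + t(C)) / 2
}

# 6x6 Voigt (Bond) transformation for stress under x_glob = Q x_loc,
# Voigt order (11, 22, 33, 23, 31, 12)
bond_matrix <- function(Q) {
  K <- matrix(0, 6, 6)
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(3, 1), c(1, 2))
  for (a in 1:6) {
    i <- idx[a, 1]; j <- idx[a, 2]
    for (b in 1:6) {
      k <- idx[b, 1]; l <- idx[b, 2]
      K[a, b] <- if (k == l) Q[i, k] * Q[j, k]
                 else Q[i, k] * Q[j, l] + Q[i, l] * Q[j, k]
    }
  }
  K
}

#' Rotate a Voigt stiffness matrix into the global frame
#'
#' `frame` holds the local material axes as columns expressed in global
#' coordinates (a proper orthonormal triad). The 6 x 6 transformation is the
#' Voigt image of the fourth-order rotation C'_pqrs = Q_pi Q_qj Q_rk Q_sl C_ijkl
#' under the package's (11, 22, 33, 23, 31, 12) engineering-shear convention.
#'
#' @param C_local 6 x 6 stiffness in the material frame, MPa.
#' @param frame 3 x 3 orthonormal matrix, det = +1, columns = material axes.
#' @return 6 x 6 stiffness in global axes.
#' @export
rotate_stiffness <- function(C_local, frame) {
  Q <- as.matrix(frame)
  if (max(abs(crossprod(Q) - diag(3))) > 1e-8 || det(Q) < 0)
    stop("`frame` must be orthonormal with det = +1")
  K <- bond_matrix(Q)
  Cg <- K %*% C_local %*% t(K)
  (Cg + t(Cg)) / 2
}

#' Isotropic Voigt stiffness from (E, nu)
#'
#' Engineering-shear convention: the shear diagonal carries the shear modulus
#' E / (2 (1 + nu)).
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @return 6 x 6 stiffness, MPa.
#' @export
isotropic_stiffness <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

#' Per-element material assignment for the three bone models
#'
#' Builds the per-element global stiffness for one of the three constitutive
#' models:
#' \describe{
#'   \item{`anisotropic`}{heterogeneous orthotropic: the fabric-based power law
#'     rotated into each element's fabric frame. Elements with rho above
#'     `card$rho_hi` become isotropic cortical bone (E = `card$E_cortical`);
#'     elements with rho at or below `card$rho_lo`, or with degenerate fabric,
#'     become isotropic with E = E0 * max(rho, rho_lo)^k.}
#'   \item{`iso_hetero`}{heterogeneous isotropic: E = E0 * clamp(rho)^k per
#'     element with the same cortical / floor rules, nu = nu0.}
#'   \item{`iso_homo`}{homogeneous isotropic: one modulus from the mean rho over
#'     solid (bone) elements, applied everywhere.}
#' }
#' The `tendon_cartilage` element set always receives the soft isotropic
#' tendon material.
#'
#' @param mesh a [tet_mesh()].
#' @param structures an [element_structure()] table covering all solid elements.
#' @param model one of `"anisotropic"`, `"iso_hetero"`, `"iso_homo"`.
#' @param card a [material_card()].
#' @return object of class `element_materials`: list with `model_tag`
#'   (character per element), `rho`, `C` (6 x 6 x m array of global
#'   stiffnesses, MPa) and `E_homo` (the homogeneous modulus, model 3 only).
#' @export
assign_materials <- function(mesh, structures, model, card = material_card()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  model <- match.arg(model, c("anisotropic", "iso_hetero", "iso_homo"))
  m_elem <- nrow(mesh$tets)
  tendon <- mesh$element_sets$tendon_cartilage
  solid <- setdiff(seq_len(m_elem), tendon)
  srow <- match(solid, structures$element)
  if (anyNA(srow)) stop("missing structures for elements: ",
                        paste(utils::head(solid[is.na(srow)], 5L), collapse = ", "))
  fabrics <- attr(structures, "fabric")

  iso_C <- function(E, nu) isotropic_stiffness(E, nu)

  C <- array(0, dim = c(6, 6, m_elem))
  tags <- character(m_elem)
  rho_out <- rep(NA_real_, m_elem)
  E_max <- 0 # largest Young's modulus assigned; sets the rod-stiffness scale

  rho_solid <- structures$rho[srow]
  E_homo <- NULL
  if (model == "iso_homo") {
    E_homo <- card$E0 * mean(rho_solid)^card$k
    C_homo <- iso_C(E_homo, card$nu0)
  }
  C_cort <- iso_C(card$E_cortical, card$nu_cortical)
  C_tendon <- iso_C(card$E_tendon, card$nu_tendon)

  for (ii in seq_along(solid)) {
    e <- solid[ii]
    rho <- rho_solid[ii]
    rho_out[e] <- rho
    if (model == "iso_homo") {
      C[, , e] <- C_homo; tags[e] <- "iso_homo"; E_max <- max(E_max, E_homo); next
    }
    if (rho > card$rho_hi) {
      C[, , e] <- C_cort; tags[e] <- "cortical"; E_max <- max(E_max, card$E_cortical); next
    }
    fab <- fabrics[[srow[ii]]]
    degen <- isTRUE(structures$degenerate[srow[ii]]) || is.null(fab)
    if (model == "iso_hetero" || rho <= card$rho_lo || degen) {
      E <- card$E0 * max(rho, card$rho_lo)^card$k
      C[, , e] <- iso_C(E, card$nu0)
      tags[e] <- if (model == "iso_hetero") "iso_hetero" else "iso_floor"
      E_max <- max(E_max, E)
      next
    }
    ec <- engineering_constants(card, rho, fab$m)
    C[, , e] <- rotate_stiffness(stiffness_matrix(ec), fab$frame)
    tags[e] <- "anisotropic"
    E_max <- max(E_max, ec$E)
  }
  for (e in tendon) {
    C[, , e] <- C_tendon; tags[e] <- "tendon"; rho_out[e] <- NA_real_
  }
  structure(list(model = model, model_tag = tags, rho = rho_out, C = C,
                 E_homo = E_homo, E_max = E_max),
            class = "element_materials")
}

#' Export element materials as CSV
#'
#' One row per element: id, model tag, rho, and the 21 independent stiffness
#' entries (upper triangle, Voigt order 11, 22, 33, 23, 31, 12), MPa.
#'
#' @param materials an [assign_materials()] result.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_materials_csv <- function(materials, path) {
  m <- dim(materials$C)[3]
  ut <- which(upper.tri(matrix(0, 6, 6), diag = TRUE))
  ord <- c("11", "22", "33", "23", "31", "12")
  cn <- outer(ord, ord, function(a, b) paste0("C", a, "_", b))[ut]
  flat <- t(vapply(seq_len(m), function(e) materials$C[, , e][ut], numeric(21)))
  colnames(flat) <- cn
  df <- cbind(data.frame(element = seq_len(m), model_tag = materials$model_tag,
                         rho = materials$rho), as.data.frame(flat))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read element materials back from CSV
#'
#' Inverse of [write_materials_csv()]: reconstructs the per-element stiffness
#' array, model tags and densities. The recorded maximum Young's modulus is not
#' part of the CSV, so a solve on re-read materials estimates the rod-stiffness
#' scale from the stiffness diagonals instead.
#'
#' @param path CSV written by [write_materials_csv()].
#' @return an `element_materials` object.
#' @export
read_materials_csv <- function(path) {
  df <- utils::read.csv(path)
  m <- nrow(df)
  ut <- which(upper.tri(matrix(0, 6, 6), diag = TRUE))
  C <- array(0, dim = c(6, 6, m))
  flat <- as.matrix(df[, -(1:3), drop = FALSE])
  if (ncol(flat) != 21L) stop("expected 21 stiffness columns, got ", ncol(flat))
  for (e in seq_len(m)) {
    Ce <- matrix(0, 6, 6)
    Ce[ut] <- flat[e, ]
    Ce <- Ce + t(Ce) - diag(diag(Ce))
    C[, , e] <- Ce
  }
  structure(list(model = "from_csv", model_tag = df$model_tag, rho = df$rho,
                 C = C, E_homo = NULL, E_max = NULL),
            class = "element_materials")
}

#' Export element materials as Abaqus *ELASTIC, TYPE=ANISOTROPIC blocks
#'
#' Writes one `*MATERIAL` / `*ELASTIC, TYPE=ANISOTROPIC` block per element.
#' Constants follow Abaqus's ordering (D1111, D1122, D2222, D1133, ...), i.e.
#' the row-wise lower triangle in Abaqus's Voigt order (11, 22, 33, 12, 13,
#' 23), converted from the package's (11, 22, 33, 23, 31, 12) convention.
#'
#' @param materials an [assign_materials()] result.
#' @param path output .inp fragment.
#' @return `path`, invisibly.
#' @export
write_materials_abaqus <- function(materials, path) {
  m <- dim(materials$C)[3]
  perm <- c(1L, 2L, 3L, 6L, 5L, 4L)  # internal order -> Abaqus (11,22,33,12,13,23)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("** fabrifem per-element anisotropic elasticity, MPa", con)
  for (e in seq_len(m)) {
    Ca <- materials$C[perm, perm, e]
    vals <- unlist(lapply(1:6, function(i) Ca[i, 1:i]))
    writeLines(sprintf("*MATERIAL, NAME=MAT_%d", e), con)
    writeLines("*ELASTIC, TYPE=ANISOTROPIC", con)
    for (r in seq(1, 21, by = 8))
      writeLines(paste(sprintf("%.6g", vals[r:min(r + 7, 21)]), collapse = ", "), con)
  }
  invisible(path)
}
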