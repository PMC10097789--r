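#' Write a tet mesh as an Abaqus .inp subset
#'
#' Emits `*NODE`, `*ELEMENT, TYPE=C3D4`, `*NSET` and `*ELSET` blocks with
#' 1-based ids, which is the convention used on disk; in memory the package
#' keeps plain 1-based R indices.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mesh_inp <- function(mesh, path) {
  stopifnot(inherits(mesh, "tet_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("tetrahedral mesh (C3D4 subset)", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.10g, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3], mesh$tets[, 4]), con)
  write_set <- function(kw, name, ids) {
    writeLines(sprintf("*%s, %s=%s", kw, kw, name), con)
    for (chunk in split(ids, ceiling(seq_along(ids) / 16)))
      writeLines(paste(chunk, collapse = ", "), con)
  }
  for (nm in names(mesh$node_sets)) write_set("NSET", nm, mesh$node_sets[[nm]])
  for (nm in names(mesh$element_sets)) write_set("ELSET", nm, mesh$element_sets[[nm]])
  invisible(path)
}

#' Read an Abaqus .inp subset into a tet mesh
#'
#' Supports `*NODE`, `*ELEMENT, TYPE=C3D4`, `*NSET`, `*ELSET` (plain id lists,
#' no GENERATE). Node and element ids on disk may be arbitrary; they are
#' remapped to dense 1-based indices in memory. Unknown keywords are skipped
#' with a warning; non-C3D4 solid element blocks are an error.
#'
#' @param path input file.
#' @return a [tet_mesh()].
#' @export
read_mesh_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "**")]
  is_kw <- startsWith(lines, "*")

  node_id <- numeric(0); node_xyz <- list()
  elem_id <- numeric(0); elem_conn <- list()
  nsets <- list(); elsets <- list()

  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!is_kw[i]) stop("parse error at line ", i, ": expected a keyword, got: ", ln)
    kw <- toupper(sub(",.*$", "", ln))
    params <- gsub(" ", "", ln)   # keyword matching is case-insensitive, but set names keep their case
    block_end <- i
    while (block_end < length(lines) && !is_kw[block_end + 1L]) block_end <- block_end + 1L
    body <- if (block_end > i) lines[(i + 1L):block_end] else character(0)
    parse_num <- function(b) lapply(strsplit(b, ","), function(x) as.numeric(trimws(x)))

    if (kw == "*NODE") {
      rows <- parse_num(body)
      node_id <- c(node_id, vapply(rows, `[`, 0, 1L))
      node_xyz <- c(node_xyz, lapply(rows, function(r) r[2:4]))
    } else if (kw == "*ELEMENT") {
      type <- toupper(sub(".*TYPE=([A-Za-z0-9]+).*", "\\1", params, ignore.case = TRUE))
      if (type != "C3D4")
        stop("unsupported element type '", type, "' at line ", i, " (only C3D4 is handled)")
      rows <- parse_num(body)
      elem_id <- c(elem_id, vapply(rows, `[`, 0, 1L))
      elem_conn <- c(elem_conn, lapply(rows, function(r) r[2:5]))
    } else if (kw == "*NSET" || kw == "*ELSET") {
      name <- sub(paste0(".*", substring(kw, 2), "=([^,]+).*"), "\\1", params,
                  ignore.case = TRUE)
      ids <- unlist(parse_num(body))
      ids <- ids[!is.na(ids)]
      if (kw == "*NSET") nsets[[name]] <- c(nsets[[name]], ids)
      else elsets[[name]] <- c(elsets[[name]], ids)
    } else if (kw == "*HEADING") {
      # free text, skip
    } else {
      warning("skipping unknown keyword block at line ", i, ": ", kw)
    }
    i <- block_end + 1L
  }

  if (length(node_id) == 0L) stop("missing *NODE section")
  if (length(elem_id) == 0L) stop("missing *ELEMENT section")
  nodes <- do.call(rbind, node_xyz)
  nmap <- integer(max(node_id)); nmap[node_id] <- seq_along(node_id)
  tets <- do.call(rbind, elem_conn)
  tets <- matrix(nmap[tets], ncol = 4L)
  emap <- integer(max(elem_id)); emap[elem_id] <- seq_along(elem_id)
  node_sets <- lapply(nsets, function(ids) sort(unname(nmap[ids])))
  element_sets <- lapply(elsets, function(ids) sort(unname(emap[ids])))
  tet_mesh(nodes, tets, node_sets = node_sets, element_sets = element_sets)
}

#' Write a legacy-ASCII VTK unstructured grid
#'
#' Point data: nodal vectors (e.g. displacement); cell data: per-element
#' scalars. Intended for visual inspection in ParaView.
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.vtk` file.
#' @param point_vectors optional named list of n x 3 matrices.
#' @param cell_scalars optional named list of length-m numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_vectors = list(), cell_scalars = list()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fabrifem output", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
    }
  }
  if (length(cell_scalars)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_scalars[[nm]]), con)
    }
  }
  invisible(path)
}
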