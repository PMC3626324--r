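#' Read a TetGen-style .node/.ele mesh pair
#'
#' Reads TetGen ASCII volume meshes. The index base (0 or 1) is taken from
#' the first node index as written in the file; connectivity is converted to
#' the package's internal 1-based convention. A per-element attribute, when
#' present, is used as the region label.
#'
#' @param path Path to the \code{.node} file, the \code{.ele} file, or the
#'   common basename.
#' @return An \code{fmt_mesh}.
#' @export
read_tetgen_mesh <- function(path) {
  base <- sub("\\.(node|ele)$", "", path)
  node_path <- paste0(base, ".node")
  ele_path <- paste0(base, ".ele")
  for (p in c(node_path, ele_path)) {
    if (!file.exists(p)) stop("I/O error: missing file ", p)
  }
  nd <- read_tetgen_table(node_path)
  hdr <- nd$header
  n <- hdr[1]
  if (length(hdr) < 2 || hdr[2] != 3) {
    stop("I/O error: ", node_path, " is not a 3D .node file")
  }
  body <- nd$body
  if (nrow(body) != n) stop("I/O error: node count mismatch in ", node_path)
  first_index <- body[1, 1]
  if (!first_index %in% c(0, 1)) {
    stop("I/O error: unsupported index base in ", node_path)
  }
  ord <- order(body[, 1])
  coords <- as.matrix(body[ord, 2:4, drop = FALSE])

  el <- read_tetgen_table(ele_path)
  m <- el$header[1]
  npt <- el$header[2]
  if (npt != 4) stop("I/O error: only linear tetrahedra supported in ", ele_path)
  eb <- el$body
  if (nrow(eb) != m) stop("I/O error: element count mismatch in ", ele_path)
  conn <- as.matrix(eb[, 2:5, drop = FALSE]) - first_index + 1L
  if (any(conn < 1) || any(conn > n)) {
    stop("I/O error: ", ele_path, " references a node beyond N")
  }
  region <- if (ncol(eb) >= 6) as.integer(eb[, 6]) else NULL
  fmt_mesh(coords, conn, region)
}

read_tetgen_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  header <- scan(text = lines[1], quiet = TRUE)
  body <- do.call(rbind, lapply(lines[-1], function(l) scan(text = l, quiet = TRUE)))
  list(header = header, body = body)
}

#' Write a mesh as a TetGen .node/.ele pair
#'
#' Writes 1-based ASCII TetGen files; region labels go into the element
#' attribute column. \code{read_tetgen_mesh(write_tetgen_mesh(...))}
#' round-trips coordinates and connectivity exactly.
#'
#' @param mesh An \code{fmt_mesh}.
#' @param base Output basename; \code{.node} and \code{.ele} are appended.
#' @return The basename, invisibly.
#' @export
write_tetgen_mesh <- function(mesh, base) {
  n <- nrow(mesh$node_coords)
  m <- nrow(mesh$tet_conn)
  node_lines <- c(
    sprintf("%d 3 0 0", n),
    sprintf("%d %.17g %.17g %.17g", seq_len(n),
            mesh$node_coords[, 1], mesh$node_coords[, 2], mesh$node_coords[, 3])
  )
  writeLines(node_lines, paste0(base, ".node"))
  ele_lines <- c(
    sprintf("%d 4 1", m),
    sprintf("%d %d %d %d %d %d", seq_len(m),
            mesh$tet_conn[, 1], mesh$tet_conn[, 2],
            mesh$tet_conn[, 3], mesh$tet_conn[, 4], mesh$region_label)
  )
  writeLines(ele_lines, paste0(base, ".ele"))
  invisible(base)
}

#' Write a mesh with per-node fields as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK, cell type 10 (tetrahedron), one SCALARS array per named
#' entry of \code{point_data}.
#'
#' @param path Output file path (conventionally \code{.vtk}).
#' @param mesh An \code{fmt_mesh}.
#' @param point_data Named list of numeric per-node vectors (e.g.
#'   \code{list(eta = ..., mu_a = ...)}).
#' @return \code{path}, invisibly.
#' @export
write_vtk_fields <- function(path, mesh, point_data = list()) {
  n <- nrow(mesh$node_coords)
  m <- nrow(mesh$tet_conn)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "earlyfmt fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$node_coords[, 1],
                     mesh$node_coords[, 2], mesh$node_coords[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tet_conn[, 1] - 1L,
                     mesh$tet_conn[, 2] - 1L, mesh$tet_conn[, 3] - 1L,
                     mesh$tet_conn[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (length(v) != n) {
        stop("I/O error: point data '", nm, "' has wrong length")
      }
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   sprintf("%.10g", v)), con)
    }
  }
  invisible(path)
}
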