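#' Tetrahedral mesh container
#'
#' Constructs a validated tetrahedral mesh. Connectivity is stored 1-based
#' (R convention). Element orientation is fixed so every signed volume is
#' strictly positive; elements supplied with negative orientation are
#' reordered. The boundary surface is extracted on construction.
#'
#' @param node_coords Numeric N x 3 matrix of node positions in cm.
#' @param tet_conn Integer M x 4 matrix of node indices per tetrahedron.
#' @param region_label Integer vector of length M; region id per element.
#' @return An object of class \code{fmt_mesh} with fields \code{node_coords},
#'   \code{tet_conn}, \code{region_label}, \code{tet_volume} (cm^3),
#'   \code{boundary_faces} (B x 3, outward oriented), \code{face_normal}
#'   (B x 3 outward unit normals), \code{face_area}, \code{nodal_volume}
#'   (per-node share, cm^3).
#' @export
fmt_mesh <- function(node_coords, tet_conn, region_label = NULL) {
  node_coords <- as.matrix(node_coords)
  storage.mode(node_coords) <- "double"
  dimnames(node_coords) <- NULL
  tet_conn <- as.matrix(tet_conn)
  storage.mode(tet_conn) <- "integer"
  dimnames(tet_conn) <- NULL
  if (ncol(node_coords) != 3) stop("mesh error: node_coords must be N x 3")
  if (ncol(tet_conn) != 4) stop("mesh error: tet_conn must be M x 4")
  n <- nrow(node_coords)
  if (any(tet_conn < 1L) || any(tet_conn > n)) {
    stop("mesh error: connectivity references a node beyond N")
  }
  if (is.null(region_label)) region_label <- rep(0L, nrow(tet_conn))
  region_label <- as.integer(region_label)
  if (length(region_label) != nrow(tet_conn)) {
    stop("mesh error: one region label per element required")
  }

  vol <- tet_signed_volumes(node_coords, tet_conn)
  flip <- which(vol < 0)
  if (length(flip)) {
    tet_conn[flip, c(3, 4)] <- tet_conn[flip, c(4, 3)]
    vol[flip] <- -vol[flip]
  }
  if (any(vol <= 0)) {
    stop("mesh error: degenerate (zero-volume) element(s) ",
         paste(utils::head(which(vol <= 0), 5), collapse = ", "))
  }

  mesh <- structure(
    list(node_coords = node_coords, tet_conn = tet_conn,
         region_label = region_label, tet_volume = vol),
    class = "fmt_mesh"
  )
  bnd <- extract_boundary(mesh)
  mesh$boundary_faces <- bnd$faces
  mesh$face_normal <- bnd$normal
  mesh$face_area <- bnd$area
  mesh$nodal_volume <- nodal_volumes(mesh)
  mesh
}

#' @export
print.fmt_mesh <- function(x, ...) {
  cat("<fmt_mesh>", nrow(x$node_coords), "nodes,",
      nrow(x$tet_conn), "tets,", nrow(x$boundary_faces), "boundary faces,",
      "volume", format(sum(x$tet_volume), digits = 6), "cm^3\n")
  invisible(x)
}

# Signed volumes of all tets, vectorised: det(p2-p1, p3-p1, p4-p1)/6.
tet_signed_volumes <- function(coords, conn) {
  p1 <- coords[conn[, 1], , drop = FALSE]
  a <- coords[conn[, 2], , drop = FALSE] - p1
  b <- coords[conn[, 3], , drop = FALSE] - p1
  d <- coords[conn[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# Per-node volume share: each tet contributes V/4 to each of its vertices.
nodal_volumes <- function(mesh) {
  v <- numeric(nrow(mesh$node_coords))
  share <- rep(mesh$tet_volume / 4, 4)
  idx <- as.vector(mesh$tet_conn)
  agg <- rowsum(share, idx)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Faces belonging to exactly one tetrahedron form the boundary; each is
#' oriented so its normal points away from the adjacent element centroid.
#'
#' @param mesh An \code{fmt_mesh} (or a bare list with \code{node_coords},
#'   \code{tet_conn}).
#' @return List with \code{faces} (B x 3 node indices, outward oriented),
#'   \code{normal} (B x 3 unit normals), \code{area} (length B, cm^2).
#' @export
extract_boundary <- function(mesh) {
  conn <- mesh$tet_conn
  coords <- mesh$node_coords
  m <- nrow(conn)
  # local faces opposite each vertex
  lf <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  faces <- do.call(rbind, lapply(1:4, function(i) conn[, lf[i, ], drop = FALSE]))
  owner <- rep(seq_len(m), 4)
  mn <- pmin(faces[, 1], faces[, 2], faces[, 3])
  mx <- pmax(faces[, 1], faces[, 2], faces[, 3])
  md <- faces[, 1] + faces[, 2] + faces[, 3] - mn - mx
  key <- paste(mn, md, mx)
  cnt <- table(key)
  if (any(cnt > 2)) {
    stop("mesh error: non-manifold face shared by more than 2 elements")
  }
  keep <- which(key %in% names(cnt)[cnt == 1])
  bfaces <- faces[keep, , drop = FALSE]
  bowner <- owner[keep]

  p1 <- coords[bfaces[, 1], , drop = FALSE]
  e1 <- coords[bfaces[, 2], , drop = FALSE] - p1
  e2 <- coords[bfaces[, 3], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(nrm^2))
  centroid_f <- (p1 + coords[bfaces[, 2], , drop = FALSE] +
                 coords[bfaces[, 3], , drop = FALSE]) / 3
  centroid_t <- (coords[conn[bowner, 1], , drop = FALSE] +
                 coords[conn[bowner, 2], , drop = FALSE] +
                 coords[conn[bowner, 3], , drop = FALSE] +
                 coords[conn[bowner, 4], , drop = FALSE]) / 4
  outward <- rowSums(nrm * (centroid_f - centroid_t))
  swap <- which(outward < 0)
  if (length(swap)) {
    bfaces[swap, c(2, 3)] <- bfaces[swap, c(3, 2)]
    nrm[swap, ] <- -nrm[swap, ]
  }
  list(faces = bfaces, normal = nrm / area2, area = area2 / 2)
}

#' Boundary node indices of a mesh
#' @param mesh An \code{fmt_mesh}.
#' @return Sorted integer vector of node indices lying on the boundary.
#' @export
boundary_nodes <- function(mesh) sort(unique(as.vector(mesh$boundary_faces)))

# Element centroids, M x 3.
tet_centroids <- function(mesh) {
  (mesh$node_coords[mesh$tet_conn[, 1], , drop = FALSE] +
   mesh$node_coords[mesh$tet_conn[, 2], , drop = FALSE] +
   mesh$node_coords[mesh$tet_conn[, 3], , drop = FALSE] +
   mesh$node_coords[mesh$tet_conn[, 4], , drop = FALSE]) / 4
}

# Nearest mesh node to a point (3-vector). Returns its index.
nearest_node <- function(mesh, point) {
  d2 <- (mesh$node_coords[, 1] - point[1])^2 +
        (mesh$node_coords[, 2] - point[2])^2 +
        (mesh$node_coords[, 3] - point[3])^2
  which.min(d2)
}
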