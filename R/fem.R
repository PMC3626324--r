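# Linear (barycentric) basis on a single tetrahedron: constant gradients and
# signed volume. coords is 4 x 3 (one vertex per row).
tet_basis <- function(coords) {
  M <- cbind(1, coords)
  V <- det(M[2:4, 2:4] - matrix(M[1, 2:4], 3, 3, byrow = TRUE)) / 6
  if (!is.finite(V) || abs(V) < .Machine$double.xmin) {
    stop("assembly error: degenerate (zero-volume) element")
  }
  grads <- t(solve(M)[2:4, , drop = FALSE])  # 4 x 3, rows sum to 0
  list(grads = grads, volume = V)
}

#' Element mass matrix of a linear tetrahedron
#'
#' The 4x4 matrix \eqn{(1/c)\int u_i u_j \, d\Omega} entering the temporal
#' term of the time-domain diffusion equation; closed form
#' \eqn{(1/c) V (1+\delta_{ij})/20}.
#'
#' @param coords 4 x 3 matrix of vertex coordinates (cm).
#' @param c Light speed in the medium, cm/ps.
#' @return 4 x 4 symmetric matrix.
#' @export
element_mass <- function(coords, c) {
  b <- tet_basis(coords)
  V <- abs(b$volume)
  (V / c) * (matrix(1, 4, 4) + diag(4)) / 20
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' Diffusion plus absorption contribution
#' \eqn{\int [D \nabla u_i \cdot \nabla u_j + \mu_a u_i u_j] d\Omega}
#' with piecewise-constant coefficients:
#' \eqn{D V (\nabla u_i\cdot\nabla u_j) + \mu_a V (1+\delta_{ij})/20}.
#'
#' @param coords 4 x 3 matrix of vertex coordinates (cm).
#' @param D Diffusion coefficient, cm.
#' @param mu_a Absorption coefficient, 1/cm.
#' @return 4 x 4 symmetric matrix.
#' @export
element_stiffness <- function(coords, D, mu_a) {
  stopifnot(D >= 0, mu_a >= 0)
  b <- tet_basis(coords)
  V <- abs(b$volume)
  D * V * (b$grads %*% t(b$grads)) +
    mu_a * V * (matrix(1, 4, 4) + diag(4)) / 20
}

#' Boundary face matrix of a linear surface triangle
#'
#' Robin boundary contribution \eqn{(1/2q)\int_{\partial\Omega} u_i u_j}
#' over one boundary triangle: \eqn{(1/(2q)) A (1+\delta_{ij})/12}.
#'
#' @param coords 3 x 3 matrix of triangle vertex coordinates (cm).
#' @param q Boundary mismatch coefficient (> 0).
#' @return 3 x 3 symmetric matrix.
#' @export
face_boundary_matrix <- function(coords, q) {
  if (!is.finite(q) || q <= 0) {
    stop("invalid optical property: q must be > 0")
  }
  e1 <- coords[2, ] - coords[1, ]
  e2 <- coords[3, ] - coords[1, ]
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  A <- sqrt(sum(nrm^2)) / 2
  if (A <= 0) stop("assembly error: degenerate boundary face")
  (A / (2 * q)) * (matrix(1, 3, 3) + diag(3)) / 12
}

# Vectorised cross product of rows of two M x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Assemble the global FEM system matrices
#'
#' Galerkin assembly over linear tetrahedra of the stiffness matrix K
#' (volume diffusion + absorption terms plus the Robin surface term
#' \eqn{1/(2q)\int_{\partial\Omega} u_i u_j}) and the mass-like matrix C
#' (\eqn{(1/c)\int u_i u_j}). Coefficients are piecewise constant per
#' element, mapped from region labels.
#'
#' @param mesh An \code{fmt_mesh}.
#' @param props An \code{fmt_properties}.
#' @param include_boundary Include the Robin surface term in K (default
#'   TRUE; disabling it is useful for null-space diagnostics).
#' @return An object of class \code{fmt_system}: list with sparse symmetric
#'   \code{K}, \code{C} (\pkg{Matrix} \code{dsCMatrix}), plus \code{mesh}
#'   and \code{props} references.
#' @export
assemble_system <- function(mesh, props, include_boundary = TRUE) {
  conn <- mesh$tet_conn
  coords <- mesh$node_coords
  n <- nrow(coords)
  pe <- region_properties(props, mesh$region_label)
  V <- mesh$tet_volume

  p1 <- coords[conn[, 1], , drop = FALSE]
  a <- coords[conn[, 2], , drop = FALSE] - p1
  b <- coords[conn[, 3], , drop = FALSE] - p1
  d <- coords[conn[, 4], , drop = FALSE] - p1
  s <- 1 / (6 * V)
  g2 <- row_cross(b, d) * s
  g3 <- row_cross(d, a) * s
  g4 <- row_cross(a, b) * s
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)

  mw <- V / 20  # mass-matrix weight: entries mw*(1+delta)
  ii <- jj <- kk <- cc <- vector("list", 16)
  t_idx <- 1L
  for (i in 1:4) {
    for (j in 1:4) {
      kij <- pe$D * V * rowSums(G[[i]] * G[[j]]) +
        pe$mu_a * mw * (1 + (i == j))
      cij <- mw * (1 + (i == j)) / props$c
      ii[[t_idx]] <- conn[, i]
      jj[[t_idx]] <- conn[, j]
      kk[[t_idx]] <- kij
      cc[[t_idx]] <- cij
      t_idx <- t_idx + 1L
    }
  }
  ii <- unlist(ii); jj <- unlist(jj)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(kk), dims = c(n, n))
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(cc), dims = c(n, n))

  if (include_boundary && nrow(mesh$boundary_faces) > 0) {
    bf <- mesh$boundary_faces
    w <- mesh$face_area / (24 * props$q)  # (A/(2q)) * (1+delta)/12
    bi <- bj <- bx <- vector("list", 9)
    t_idx <- 1L
    for (i in 1:3) {
      for (j in 1:3) {
        bi[[t_idx]] <- bf[, i]
        bj[[t_idx]] <- bf[, j]
        bx[[t_idx]] <- w * (1 + (i == j))
        t_idx <- t_idx + 1L
      }
    }
    K <- K + Matrix::sparseMatrix(i = unlist(bi), j = unlist(bj),
                                  x = unlist(bx), dims = c(n, n))
  }

  structure(
    list(K = Matrix::forceSymmetric(K), C = Matrix::forceSymmetric(C),
         mesh = mesh, props = props),
    class = "fmt_system"
  )
}

#' @export
print.fmt_system <- function(x, ...) {
  cat("<fmt_system> N =", nrow(x$K), "nodes;",
      length(x$K@x), "stored K entries\n")
  invisible(x)
}

#' Dump system matrices in Matrix Market format
#' @param system An \code{fmt_system}.
#' @param base Output basename; writes \code{<base>_K.mtx}, \code{<base>_C.mtx}.
#' @return The basename, invisibly.
#' @export
write_system_mtx <- function(system, base) {
  Matrix::writeMM(methods::as(system$K, "generalMatrix"), paste0(base, "_K.mtx"))
  Matrix::writeMM(methods::as(system$C, "generalMatrix"), paste0(base, "_C.mtx"))
  invisible(base)
}
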