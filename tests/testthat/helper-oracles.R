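# Independent numerical oracles used across the suite. These deliberately
# use different algorithms / integration rules than the package code.

# Degree-2 exact Gaussian quadrature on a tetrahedron (4 interior points).
quad_tet <- function(coords, f) {
  a <- 0.5854101966249685
  b <- 0.1381966011250105
  bary <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  v <- abs(det(cbind(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ],
                     coords[4, ] - coords[1, ]))) / 6
  s <- 0
  for (p in seq_len(4)) {
    lam <- bary[p, ]
    x <- as.numeric(lam %*% coords)
    s <- s + f(x, lam)
  }
  s * v / 4
}

# Quadrature version of the element mass matrix (1/c) int u_i u_j.
oracle_element_mass <- function(coords, cc) {
  M <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      M[i, j] <- quad_tet(coords, function(x, lam) lam[i] * lam[j]) / cc
    }
  }
  M
}

# Quadrature version of the element stiffness D grad.grad + mu_a u u.
oracle_element_stiffness <- function(coords, D, mu_a) {
  Minv <- solve(cbind(1, coords))
  grads <- t(Minv[2:4, , drop = FALSE])
  K <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      K[i, j] <- quad_tet(coords, function(x, lam) {
        D * sum(grads[i, ] * grads[j, ]) + mu_a * lam[i] * lam[j]
      })
    }
  }
  K
}

# Degree-2 exact edge-midpoint rule on a triangle for the Robin face term.
oracle_face_mass <- function(coords, q) {
  e1 <- coords[2, ] - coords[1, ]
  e2 <- coords[3, ] - coords[1, ]
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  A <- sqrt(sum(nrm^2)) / 2
  mids <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  M <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      M[i, j] <- sum(mids[, i] * mids[, j]) * A / 3 / (2 * q)
    }
  }
  M
}

# Direct O(T^2) double-sum convolution oracle, scatter (j-outer) loop order.
oracle_convolve <- function(a, b, dt) {
  T_ <- length(a)
  out <- numeric(T_)
  for (j in seq_len(T_)) {
    for (k in j:T_) {
      out[k] <- out[k] + a[j] * b[k - j + 1L]
    }
  }
  dt * out
}

# Random non-degenerate tetrahedron / triangle generators.
random_tet <- function() {
  repeat {
    co <- matrix(stats::runif(12, -1, 1), 4, 3)
    v <- det(cbind(co[2, ] - co[1, ], co[3, ] - co[1, ], co[4, ] - co[1, ])) / 6
    if (abs(v) > 1e-3) return(co)
  }
}
random_triangle <- function() {
  repeat {
    co <- matrix(stats::runif(9, -1, 1), 3, 3)
    e1 <- co[2, ] - co[1, ]
    e2 <- co[3, ] - co[1, ]
    n2 <- sum((c(e1[2] * e2[3] - e1[3] * e2[2],
                 e1[3] * e2[1] - e1[1] * e2[3],
                 e1[1] * e2[2] - e1[2] * e2[1]))^2)
    if (sqrt(n2) / 2 > 1e-3) return(co)
  }
}

# Minimal meshes built by hand.
single_tet_mesh <- function() {
  fmt_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1, 4))
}
two_tet_mesh <- function() {
  # two tets sharing face (1,2,3)
  fmt_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(0.4, 0.4, -1)),
           rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 5L)))
}

# A 1-node scalar "system" for recurrence oracles (K, C given directly).
scalar_system <- function(k0, c0, cc = 1) {
  structure(
    list(K = Matrix::forceSymmetric(Matrix::Matrix(k0, 1, 1, sparse = TRUE)),
         C = Matrix::forceSymmetric(Matrix::Matrix(c0, 1, 1, sparse = TRUE)),
         props = list(c = cc)),
    class = "fmt_system"
  )
}

# Memoised small/fast phantom + assembled operators shared across tests.
.fixture_env <- new.env(parent = emptyenv())
small_setup <- function() {
  if (is.null(.fixture_env$small)) {
    sp <- phantom_spec(edge_length_cm = 0.4, refine_factor = 2)
    ph <- build_cylindrical_phantom(sp)
    sys <- assemble_system(ph$mesh, ph$props)
    tg <- make_time_grid(10, 300, 300)
    prop <- make_propagator(sys, tg$dt)
    .fixture_env$small <- list(ph = ph, sys = sys, tg = tg, prop = prop)
  }
  .fixture_env$small
}

# Small homogeneous symmetric cylinder (no organs, no target refinement).
homog_setup <- function() {
  if (is.null(.fixture_env$homog)) {
    sp <- phantom_spec(organs = list(), edge_length_cm = 0.4,
                       refine_target = FALSE)
    ph <- build_cylindrical_phantom(sp)
    sys <- assemble_system(ph$mesh, ph$props)
    tg <- make_time_grid(10, 300, 300)
    prop <- make_propagator(sys, tg$dt)
    .fixture_env$homog <- list(ph = ph, sys = sys, tg = tg, prop = prop)
  }
  .fixture_env$homog
}
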