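#' Discrete time grid for implicit time stepping
#'
#' Time nodes are \eqn{t_k = k \Delta t}, \eqn{k = 1 \dots T} (the field is
#' identically zero at and before \eqn{t = 0}). The reconstruction gate is
#' snapped to the nearest time node, with a warning when snapping moves it.
#'
#' @param dt Time step, ps.
#' @param t_end End of the simulated window, ps.
#' @param gate_time Reconstruction gate, ps (early-photon gate; default
#'   setup uses 300 ps).
#' @return Object of class \code{fmt_time_grid}: \code{dt}, \code{n_steps},
#'   \code{gate_index} (1-based time-node index), \code{times} (ps),
#'   \code{gate_time} (snapped, ps).
#' @export
make_time_grid <- function(dt, t_end, gate_time = t_end) {
  if (!is.finite(dt) || dt <= 0) stop("configuration error: dt must be > 0")
  if (gate_time > t_end) {
    stop("configuration error: gate_time exceeds t_end")
  }
  if (gate_time < dt) stop("configuration error: gate_time earlier than dt")
  n_steps <- max(1L, as.integer(round(t_end / dt)))
  gate_index <- max(1L, min(n_steps, as.integer(round(gate_time / dt))))
  snapped <- gate_index * dt
  if (abs(snapped - gate_time) > 1e-9 * max(1, gate_time)) {
    warning("gate_time ", gate_time, " ps snapped to time node ",
            gate_index, " (", snapped, " ps)")
  }
  structure(
    list(dt = dt, n_steps = n_steps, gate_index = gate_index,
         times = seq_len(n_steps) * dt, gate_time = snapped),
    class = "fmt_time_grid"
  )
}

#' Fluorophore lifetime kernel
#'
#' Samples the exponential emission decay \eqn{E(t) = \exp(-t/\tau)} on the
#' lag grid \eqn{t = 0, \Delta t, \dots, (T-1)\Delta t} used by
#' [temporal_convolve()] (the first sample is the zero-lag value 1).
#'
#' @param tau Fluorescence lifetime, ps (> 0).
#' @param time_grid An [make_time_grid()] object.
#' @return Numeric vector of length \code{n_steps}.
#' @export
lifetime_kernel <- function(tau, time_grid) {
  if (!is.finite(tau) || tau <= 0) {
    stop("invalid optical property: tau must be > 0")
  }
  exp(-(seq_len(time_grid$n_steps) - 1) * time_grid$dt / tau)
}

#' Round numeric data to IEEE single precision
#'
#' Storage-level emulation of single-precision arithmetic: values pass
#' through a 4-byte float representation and back. Used by the
#' precision-parameterized pipeline stages.
#'
#' @param x Numeric vector, matrix or array.
#' @return \code{x} with every value rounded to the nearest float32.
#' @export
as_single <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               what = "numeric", n = length(x), size = 4L)
  dim(y) <- d
  y
}

#' Precompute the implicit time-stepping propagator
#'
#' Factorizes \eqn{A = K + C/\Delta t} once (sparse Cholesky); the
#' factorization is then reused for every source, detector-adjoint and time
#' step. Equivalent to precomputing the matrix inverse, but better
#' conditioned.
#'
#' @param system An [assemble_system()] result.
#' @param dt Time step, ps.
#' @return Object of class \code{fmt_propagator} with the factorization,
#'   the scaled mass matrix \code{Cdt = C/dt} and call-count
#'   instrumentation (\code{counts$factorizations}, \code{counts$solves}).
#' @export
make_propagator <- function(system, dt) {
  if (!is.finite(dt) || dt <= 0) stop("configuration error: dt must be > 0")
  A <- system$K + system$C / dt
  counts <- new.env(parent = emptyenv())
  counts$factorizations <- 1L
  counts$solves <- 0L
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  structure(
    list(chol = ch, Cdt = system$C / dt, dt = dt, n = nrow(system$K),
         counts = counts),
    class = "fmt_propagator"
  )
}

# One exact solve A x = b against the precomputed factorization.
propagator_solve <- function(prop, b) {
  prop$counts$solves <- prop$counts$solves + 1L
  as.matrix(Matrix::solve(prop$chol, b, system = "A"))
}

#' Place a point source one transport mean free path inside the surface
#'
#' The physical surface illumination point is displaced by \eqn{1/\mu_s'}
#' along the inward boundary normal and snapped to the nearest mesh node,
#' where an impulsive unit delta load is applied at the first time step.
#'
#' @param mesh An \code{fmt_mesh}.
#' @param surface_point 3-vector on (or near) the boundary, cm.
#' @param props An \code{fmt_properties}; \eqn{\mu_s'} is taken from the
#'   region of the boundary element nearest the point.
#' @return Object of class \code{fmt_source}: \code{node} (anchor index),
#'   \code{surface_point}, \code{depth} (cm), \code{kind = "excitation"}.
#' @export
point_source_vector <- function(mesh, surface_point, props) {
  fc <- (mesh$node_coords[mesh$boundary_faces[, 1], , drop = FALSE] +
         mesh$node_coords[mesh$boundary_faces[, 2], , drop = FALSE] +
         mesh$node_coords[mesh$boundary_faces[, 3], , drop = FALSE]) / 3
  d2 <- (fc[, 1] - surface_point[1])^2 + (fc[, 2] - surface_point[2])^2 +
        (fc[, 3] - surface_point[3])^2
  fi <- which.min(d2)
  nrm <- mesh$face_normal[fi, ]
  # region of an element owning this face: use the label of the element
  # containing the opposing node; fall back to background lookup
  face_nodes <- mesh$boundary_faces[fi, ]
  owner <- which(rowSums(matrix(mesh$tet_conn %in% face_nodes,
                                nrow(mesh$tet_conn), 4)) == 3)[1]
  lbl <- if (is.na(owner)) 0L else mesh$region_label[owner]
  musp <- region_properties(props, lbl)$mu_s_prime
  depth <- 1 / musp
  target <- surface_point - depth * nrm
  node <- nearest_node(mesh, target)
  snap_dist <- sqrt(sum((mesh$node_coords[node, ] - target)^2))
  if (snap_dist > 4 * depth + 1e-9) {
    stop("placement error: displaced source point lies outside the mesh")
  }
  structure(
    list(node = node, surface_point = surface_point, depth = depth,
         kind = "excitation",
         anchor_coord = mesh$node_coords[node, ]),
    class = "fmt_source"
  )
}

# Normalise the many accepted source forms into a slot-lookup closure:
# f(k) returns the length-n load applied while stepping to time node k,
# or NULL when zero. Accepted: fmt_source (impulse at the first step),
# a node index, or a dense n x T matrix of per-step loads.
source_slot_fun <- function(source, n, n_steps) {
  if (inherits(source, "fmt_source")) {
    node <- source$node
    return(function(k) if (k == 1L) {
      s <- numeric(n); s[node] <- 1; s
    } else NULL)
  }
  if (is.numeric(source) && length(source) == 1L) {
    node <- as.integer(source)
    return(function(k) if (k == 1L) {
      s <- numeric(n); s[node] <- 1; s
    } else NULL)
  }
  if (is.matrix(source)) {
    if (nrow(source) != n || ncol(source) != n_steps) {
      stop("dimension error: source series must be N x n_steps")
    }
    return(function(k) source[, k])
  }
  stop("dimension error: unsupported source specification")
}

#' Propagate a source through the time-domain diffusion model
#'
#' Implicit time stepping \eqn{(K + C/\Delta t) G_{k+1} = (C/\Delta t) G_k +
#' S_k} from \eqn{G_0 = 0}, using the precomputed factorization. A unit
#' impulse load in the first step represents a \eqn{\delta(t)} source of
#' integrated strength \eqn{\Delta t} (the magnitude cancels in the
#' normalized Born ratio).
#'
#' @param prop An [make_propagator()] object.
#' @param time_grid An [make_time_grid()] object.
#' @param source An \code{fmt_source}, a node index (impulse), or a dense
#'   N x n_steps matrix of per-step loads.
#' @param precision \code{"double"} or \code{"single"}; single rounds the
#'   state to float32 after every step.
#' @param kind Field kind recorded on the result
#'   (\code{"excitation"}/\code{"detector_adjoint"}/\code{"emission"}).
#' @return Object of class \code{fmt_greens}: \code{values} (N x n_steps),
#'   \code{dt}, \code{kind}, \code{anchor}.
#' @export
propagate <- function(prop, time_grid, source, precision = "double",
                      kind = "excitation") {
  n <- prop$n
  T_ <- time_grid$n_steps
  slot <- source_slot_fun(source, n, T_)
  G <- matrix(0, n, T_)
  g <- numeric(n)
  for (k in seq_len(T_)) {
    rhs <- as.numeric(prop$Cdt %*% g)
    s <- slot(k)
    if (!is.null(s)) rhs <- rhs + s
    g <- propagator_solve(prop, rhs)[, 1]
    if (precision == "single") g <- as_single(g)
    if (any(!is.finite(g))) {
      stop("numerical failure: non-finite field values at time step ", k)
    }
    G[, k] <- g
  }
  anchor <- if (inherits(source, "fmt_source")) source$node
            else if (is.numeric(source) && length(source) == 1L) as.integer(source)
            else NA_integer_
  structure(list(values = G, dt = time_grid$dt, kind = kind, anchor = anchor),
            class = "fmt_greens")
}

#' @export
print.fmt_greens <- function(x, ...) {
  cat("<fmt_greens>", x$kind, "field,", nrow(x$values), "nodes x",
      ncol(x$values), "time nodes, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Batched detector-adjoint Green's functions
#'
#' Advances one multi-column state (one column per detector) one time node
#' at a time -- every detector shares the single precomputed factorization
#' -- and then restructures the result into per-detector N x T fields.
#' Numerically equivalent to calling [propagate()] per detector.
#'
#' @param prop An [make_propagator()] object.
#' @param time_grid An [make_time_grid()] object.
#' @param anchor_nodes Integer vector of detector anchor node indices.
#'   Duplicates are dropped with a warning.
#' @param precision \code{"double"} or \code{"single"}.
#' @return Object of class \code{fmt_greens_stack}: \code{values} array of
#'   dim \code{c(N, n_steps, n_detectors)}, \code{anchors}, \code{dt}.
#' @export
batched_detector_fields <- function(prop, time_grid, anchor_nodes,
                                    precision = "double") {
  anchor_nodes <- as.integer(anchor_nodes)
  if (anyDuplicated(anchor_nodes)) {
    warning("duplicate detector anchor nodes deduplicated")
    anchor_nodes <- unique(anchor_nodes)
  }
  n <- prop$n
  T_ <- time_grid$n_steps
  nd <- length(anchor_nodes)
  out <- array(0, dim = c(n, T_, nd))
  X <- matrix(0, n, nd)
  for (k in seq_len(T_)) {
    rhs <- as.matrix(prop$Cdt %*% X)
    if (k == 1L) {
      rhs[cbind(anchor_nodes, seq_len(nd))] <-
        rhs[cbind(anchor_nodes, seq_len(nd))] + 1
    }
    X <- propagator_solve(prop, rhs)
    if (precision == "single") X <- as_single(X)
    if (any(!is.finite(X))) {
      stop("numerical failure: non-finite field values at time step ", k)
    }
    out[, k, ] <- X
  }
  structure(list(values = out, anchors = anchor_nodes, dt = time_grid$dt,
                 kind = "detector_adjoint"),
            class = "fmt_greens_stack")
}
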