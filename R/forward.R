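#' Causal temporal convolution of two sampled time series
#'
#' Discrete Riemann approximation of the continuous temporal convolution:
#' \code{out[k] = dt * sum_{j=1..k} a[j] * b[k-j+1]} (1-based; \code{b[1]}
#' is the zero-lag sample). Output length equals input length (truncated
#' causal convolution). Implemented as the direct double sum.
#'
#' @param a,b Numeric vectors of equal length, sampled with step \code{dt}.
#' @param dt Time step, ps.
#' @return Numeric vector of the same length.
#' @export
temporal_convolve <- function(a, b, dt) {
  if (length(a) != length(b)) {
    stop("dimension error: series lengths differ")
  }
  T_ <- length(a)
  out <- numeric(T_)
  for (k in seq_len(T_)) {
    s <- 0
    for (j in seq_len(k)) s <- s + a[j] * b[k - j + 1L]
    out[k] <- dt * s
  }
  out
}

# Row-wise causal convolution of every row of M (N x T) with kernel
# (length T), dt-scaled. Matrix-product formulation of temporal_convolve.
convolve_rows <- function(M, kernel, dt) {
  T_ <- ncol(M)
  if (length(kernel) != T_) stop("dimension error: kernel length mismatch")
  out <- matrix(0, nrow(M), T_)
  for (k in seq_len(T_)) {
    out[, k] <- dt * (M[, seq_len(k), drop = FALSE] %*% kernel[k:1])
  }
  out
}

#' Born weight-matrix rows for one excitation source
#'
#' For each detector d and mesh node n the gated weight entry is the triple
#' temporal convolution of the excitation Green's function, the lifetime
#' kernel and the mass-weighted detector-adjoint Green's function,
#' \deqn{W[(s,d), n] = \frac{c}{\tau\,\Delta t}\,
#'   \big(G_s[n,\cdot] * E * (C G_d)[n,\cdot]\big)\big|_{t_{gate}},}
#' the discrete adjoint identity that makes \code{W \%*\% eta} reproduce the
#' coupled forward model exactly (the emission equation is linear in the
#' yield \eqn{\eta}). Rows over nodes are computed independently
#' (order-invariant).
#'
#' @param gs Excitation \code{fmt_greens} field for the source.
#' @param gd An \code{fmt_greens_stack} (or single \code{fmt_greens}) of
#'   detector-adjoint fields.
#' @param kernel Lifetime kernel from [lifetime_kernel()].
#' @param time_grid The shared [make_time_grid()] object.
#' @param system The assembled [assemble_system()] (provides C and c).
#' @param tau Fluorophore lifetime, ps.
#' @param precision \code{"double"} or \code{"single"}.
#' @return Matrix with one row per detector, one column per mesh node.
#' @export
build_weight_matrix <- function(gs, gd, kernel, time_grid, system, tau,
                                precision = "double") {
  g <- time_grid$gate_index
  if (g > time_grid$n_steps) stop("configuration error: missing gate index")
  if (!is.finite(tau) || tau <= 0) {
    stop("invalid optical property: tau must be > 0")
  }
  Q <- convolve_rows(gs$values, kernel, time_grid$dt)
  if (precision == "single") Q <- as_single(Q)
  gd_vals <- if (inherits(gd, "fmt_greens_stack")) gd$values
             else array(gd$values, dim = c(dim(gd$values), 1L))
  nd <- dim(gd_vals)[3]
  W <- matrix(0, nd, nrow(Q))
  for (d in seq_len(nd)) {
    H <- system$props$c * as.matrix(system$C %*% gd_vals[, , d])
    if (precision == "single") H <- as_single(H)
    w <- rowSums(Q[, seq_len(g), drop = FALSE] *
                 H[, g:1, drop = FALSE]) / tau
    if (precision == "single") w <- as_single(w)
    W[d, ] <- w
  }
  W
}

#' Emission source series driven by an excitation field
#'
#' Fluorescence re-emission load \eqn{S_m(\cdot,k) = C\,c\,(\eta/\tau)
#' \odot (G_x * E)[\cdot,k]}: the nodal emission density (excitation field
#' convolved with the lifetime decay, scaled by yield over lifetime) is
#' distributed through the mass matrix.
#'
#' @param eta Per-node fluorescence yield (length N, >= 0).
#' @param tau Lifetime, ps.
#' @param gx Excitation \code{fmt_greens} field.
#' @param kernel Lifetime kernel sampled on the same grid.
#' @param system The assembled system (provides C and c).
#' @param dt Time step, ps.
#' @return Dense N x n_steps matrix of per-step loads.
#' @export
emission_source_series <- function(eta, tau, gx, kernel, system, dt) {
  if (!is.finite(tau) || tau <= 0) {
    stop("invalid optical property: tau must be > 0")
  }
  if (length(eta) != nrow(gx$values)) {
    stop("dimension error: eta length must match node count")
  }
  Q <- convolve_rows(gx$values, kernel, dt)
  scaled <- (system$props$c * eta / tau) * Q
  as.matrix(system$C %*% scaled)
}

#' Simulate time-resolved measurements for an acquisition layout
#'
#' Full coupled forward model: for each excitation source the excitation
#' field is propagated, the emission load is formed from it, and a second
#' propagation yields the fluorescence field; both are sampled at the
#' detector anchor nodes across all time nodes.
#'
#' @param prop Precomputed [make_propagator()].
#' @param time_grid Shared time grid.
#' @param layout Acquisition layout from [build_acquisition()] (list of
#'   projections, each with \code{source} and \code{det_anchors}).
#' @param eta Per-node fluorescence yield.
#' @param tau Lifetime, ps.
#' @param system The assembled system.
#' @return Object of class \code{fmt_measurements}: per-projection list
#'   with \code{anchors}, \code{phix}, \code{phim} (detectors x time
#'   nodes), plus the time grid.
#' @export
simulate_measurements <- function(prop, time_grid, layout, eta, tau, system) {
  kernel <- lifetime_kernel(tau, time_grid)
  out <- lapply(layout, function(pr) {
    gx <- propagate(prop, time_grid, pr$source, kind = "excitation")
    sm <- emission_source_series(eta, tau, gx, kernel, system, time_grid$dt)
    gm <- propagate(prop, time_grid, sm, kind = "emission")
    list(anchors = pr$det_anchors,
         phix = gx$values[pr$det_anchors, , drop = FALSE],
         phim = gm$values[pr$det_anchors, , drop = FALSE])
  })
  structure(list(projections = out, time_grid = time_grid),
            class = "fmt_measurements")
}

#' @export
print.fmt_measurements <- function(x, ...) {
  nd <- vapply(x$projections, function(p) length(p$anchors), integer(1))
  cat("<fmt_measurements>", length(x$projections), "projections,",
      sum(nd), "source-detector pairs,", x$time_grid$n_steps, "time nodes\n")
  invisible(x)
}

#' Add proportional Gaussian noise to gated measurement data
#'
#' Each gated fluorescence value v becomes \code{v * (1 + level * z)} with
#' \code{z ~ N(0, 1)}; deterministic under a fixed seed. \code{level = 0.1}
#' is 10\% zero-mean proportional Gaussian noise.
#'
#' @param measurements An \code{fmt_measurements} object (only the gate
#'   column of the fluorescence data is perturbed) or a numeric vector.
#' @param level Noise fraction (>= 0).
#' @param seed Integer seed.
#' @return Object of the same type with perturbed values.
#' @export
add_noise <- function(measurements, level, seed) {
  if (level < 0) stop("configuration error: noise level must be >= 0")
  if (is.numeric(measurements)) {
    if (level == 0) return(measurements)
    set.seed(seed)
    return(measurements * (1 + level * stats::rnorm(length(measurements))))
  }
  stopifnot(inherits(measurements, "fmt_measurements"))
  if (level == 0) return(measurements)
  set.seed(seed)
  g <- measurements$time_grid$gate_index
  measurements$projections <- lapply(measurements$projections, function(p) {
    z <- stats::rnorm(length(p$anchors))
    p$phim[, g] <- p$phim[, g] * (1 + level * z)
    p
  })
  measurements
}

#' Assemble the gated normalized-Born linear system
#'
#' Stacks weight rows over all projections, divides each row and its
#' right-hand side by that pair's gated excitation measurement
#' (\eqn{\Phi_{nB} = \Phi_m / \Phi_x} at the gate), and excludes pairs
#' whose gated excitation falls below \code{floor} times the maximum over
#' pairs. Excluded pairs are flagged, never silently dropped.
#'
#' @param weight_rows List (one per projection) of matrices from
#'   [build_weight_matrix()], row-aligned with the projection's detectors.
#' @param measurements An \code{fmt_measurements} (possibly noisy).
#' @param time_grid Shared time grid.
#' @param floor Relative validity floor on the gated excitation
#'   (default 1e-9).
#' @param precision \code{"double"} or \code{"single"}.
#' @return Object of class \code{fmt_weight_system}: \code{W} (usable pairs
#'   x nodes), \code{b}, \code{pairs} (data frame with projection, anchor,
#'   usable flag, gated phix/phim), \code{n_excluded}.
#' @export
normalized_born <- function(weight_rows, measurements, time_grid,
                            floor = 1e-9, precision = "double") {
  g <- time_grid$gate_index
  projs <- measurements$projections
  stopifnot(length(weight_rows) == length(projs))
  phix <- unlist(lapply(projs, function(p) p$phix[, g]))
  phim <- unlist(lapply(projs, function(p) p$phim[, g]))
  proj_id <- rep(seq_along(projs),
                 vapply(projs, function(p) length(p$anchors), integer(1)))
  anchors <- unlist(lapply(projs, function(p) p$anchors))
  W_all <- do.call(rbind, weight_rows)

  usable <- phix > 0 & phix >= floor * max(phix)
  if (!any(usable)) {
    stop("degenerate system: all source-detector pairs fall below the ",
         "excitation validity floor")
  }
  W <- W_all[usable, , drop = FALSE] / phix[usable]
  b <- phim[usable] / phix[usable]
  if (precision == "single") {
    W <- as_single(W)
    b <- as_single(b)
  }
  structure(
    list(W = W, b = b,
         pairs = data.frame(projection = proj_id, anchor = anchors,
                            usable = usable, phix_gate = phix,
                            phim_gate = phim),
         n_excluded = sum(!usable)),
    class = "fmt_weight_system"
  )
}

#' @export
print.fmt_weight_system <- function(x, ...) {
  cat("<fmt_weight_system>", nrow(x$W), "usable pairs x", ncol(x$W),
      "nodes (", x$n_excluded, "pairs excluded )\n")
  invisible(x)
}
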