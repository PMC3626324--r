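#' ART (relaxed Kaczmarz) configuration
#'
#' @param relaxation Relaxation parameter lambda in (0, 2]; the early-gate
#'   reconstruction setup uses 0.1.
#' @param n_iterations Number of full sweeps over the rows (default 100).
#' @param nonneg Clamp negative components to zero after every row update.
#' @param row_order \code{"fixed"} (source-major, detector-minor order as
#'   assembled) or \code{"random"} (seeded permutation per sweep).
#' @param seed Seed for the random row order.
#' @param row_norm_floor Rows with squared norm below this are skipped.
#' @return Object of class \code{fmt_art_config}.
#' @export
art_config <- function(relaxation = 0.1, n_iterations = 100, nonneg = TRUE,
                       row_order = c("fixed", "random"), seed = 1L,
                       row_norm_floor = 1e-30) {
  if (!is.finite(relaxation) || relaxation <= 0 || relaxation > 2) {
    stop("configuration error: relaxation must lie in (0, 2]")
  }
  if (n_iterations < 1) stop("configuration error: n_iterations must be >= 1")
  structure(
    list(relaxation = relaxation, n_iterations = as.integer(n_iterations),
         nonneg = isTRUE(nonneg), row_order = match.arg(row_order),
         seed = as.integer(seed), row_norm_floor = row_norm_floor),
    class = "fmt_art_config"
  )
}

#' Solve the gated normalized-Born system by nonnegative ART
#'
#' Relaxed Kaczmarz row-action iterations starting from eta = 0: for each
#' row i, \code{eta <- eta + lambda * (b_i - w_i . eta) / ||w_i||^2 * w_i},
#' followed (when \code{nonneg}) by clamping negative components to zero.
#' Rows below the squared-norm floor are skipped and counted.
#'
#' Two numerical options refine the iteration without changing the row
#' update: \code{column_scale} solves for the scaled unknown
#' \code{u = column_scale * eta} (passing nodal volume shares makes the
#' Kaczmarz geometry act on nodal fluorophore mass, which removes the bias
#' of graded meshes toward large-volume nodes), and \code{support}
#' restricts the solution to a subset of nodes (all others are fixed at
#' zero, e.g. nodes closer to the boundary than one transport mean free
#' path, where the diffusion kernel is invalid).
#'
#' @param system An \code{fmt_weight_system} (or any list with matrix
#'   \code{W} and vector \code{b}).
#' @param config An [art_config()].
#' @param column_scale Optional positive per-node scale for the unknown
#'   (NULL = identity, the plain Kaczmarz update on eta).
#' @param support Optional logical/integer vector of nodes allowed to be
#'   nonzero (NULL = all).
#' @return Object of class \code{fmt_recon}: \code{eta_hat} (per node),
#'   \code{residual_history} (RHS residual norm per sweep),
#'   \code{skipped_rows}, \code{config}.
#' @export
art_solve <- function(system, config = art_config(), column_scale = NULL,
                      support = NULL) {
  W <- system$W
  b <- system$b
  stopifnot(is.matrix(W), length(b) == nrow(W))
  n_full <- ncol(W)
  if (!is.null(column_scale)) {
    if (length(column_scale) != n_full || any(column_scale <= 0)) {
      stop("configuration error: column_scale must be positive per node")
    }
    W <- sweep(W, 2, column_scale, "/")
  }
  sup_idx <- seq_len(n_full)
  if (!is.null(support)) {
    sup_idx <- if (is.logical(support)) which(support) else as.integer(support)
    if (!length(sup_idx)) stop("degenerate system: empty support")
    W <- W[, sup_idx, drop = FALSE]
  }
  nrm2 <- rowSums(W^2)
  active <- which(nrm2 >= config$row_norm_floor)
  if (!length(active)) {
    stop("degenerate system: all rows below the norm floor")
  }
  Wt <- t(W)  # column access per row update
  eta <- numeric(ncol(W))
  res <- numeric(config$n_iterations)
  if (config$row_order == "random") set.seed(config$seed)
  lam <- config$relaxation
  for (it in seq_len(config$n_iterations)) {
    ord <- if (config$row_order == "random") sample(active) else active
    for (i in ord) {
      w <- Wt[, i]
      r <- b[i] - sum(w * eta)
      eta <- eta + (lam * r / nrm2[i]) * w
      if (config$nonneg) eta[eta < 0] <- 0
    }
    res[it] <- sqrt(sum((as.numeric(W %*% eta) - b)^2))
  }
  eta_full <- numeric(n_full)
  eta_full[sup_idx] <- eta
  if (!is.null(column_scale)) eta_full <- eta_full / column_scale
  structure(
    list(eta_hat = eta_full, residual_history = res,
         skipped_rows = nrow(W) - length(active), config = config),
    class = "fmt_recon"
  )
}

#' Depth of each mesh node below the boundary surface
#'
#' Distance from every node to the nearest boundary node; boundary nodes
#' have depth 0. Used to restrict the reconstruction support to the region
#' where the diffusion approximation is valid.
#'
#' @param mesh An \code{fmt_mesh}.
#' @return Numeric vector of depths, cm.
#' @export
node_boundary_depth <- function(mesh) {
  bi <- boundary_nodes(mesh)
  bc <- mesh$node_coords[bi, , drop = FALSE]
  co <- mesh$node_coords
  depth <- numeric(nrow(co))
  interior <- setdiff(seq_len(nrow(co)), bi)
  # chunked pairwise distances to keep memory bounded
  for (chunk in split(interior, ceiling(seq_along(interior) / 2000))) {
    d2 <- outer(rowSums(co[chunk, , drop = FALSE]^2), rowSums(bc^2), "+") -
      2 * co[chunk, , drop = FALSE] %*% t(bc)
    depth[chunk] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  depth
}

#' @export
print.fmt_recon <- function(x, ...) {
  cat("<fmt_recon>", length(x$eta_hat), "nodes; final residual",
      format(utils::tail(x$residual_history, 1), digits = 5), ";",
      x$skipped_rows, "rows skipped\n")
  invisible(x)
}

#' Maximum node-wise relative error between two reconstructions
#'
#' \code{max |eta_ref - eta_test| / eta_ref * 100} over the support of the
#' reference, i.e. nodes where \code{eta_ref >= support_floor *
#' max(eta_ref)}. Used to compare single- against double-precision
#' pipelines.
#'
#' @param eta_ref Reference reconstruction (per node).
#' @param eta_test Comparison reconstruction (same length).
#' @param support_floor Relative support threshold (default 0.01).
#' @return Maximum relative error in percent.
#' @export
max_relative_error <- function(eta_ref, eta_test, support_floor = 0.01) {
  if (length(eta_ref) != length(eta_test)) {
    stop("dimension error: reconstruction lengths differ")
  }
  sup <- which(eta_ref >= support_floor * max(eta_ref) & eta_ref > 0)
  if (!length(sup)) stop("metric error: empty reconstruction support")
  max(abs(eta_ref[sup] - eta_test[sup]) / eta_ref[sup]) * 100
}

#' Localization error of a reconstructed target
#'
#' Euclidean distance between the yield-weighted centroid of the nodes
#' above half of the reconstruction maximum and the true target centre.
#'
#' @param eta_hat Reconstructed per-node yield.
#' @param mesh The \code{fmt_mesh} (for node coordinates), or an N x 3
#'   coordinate matrix.
#' @param true_center 3-vector, cm.
#' @return Distance in cm.
#' @export
localization_error <- function(eta_hat, mesh, true_center) {
  coords <- if (inherits(mesh, "fmt_mesh")) mesh$node_coords else as.matrix(mesh)
  if (all(eta_hat == 0)) stop("metric error: all-zero reconstruction")
  mask <- eta_hat >= 0.5 * max(eta_hat)
  w <- eta_hat[mask]
  centroid <- colSums(coords[mask, , drop = FALSE] * w) / sum(w)
  sqrt(sum((centroid - true_center)^2))
}

#' Fraction of recovered yield mass near the true centre
#'
#' Volume-weighted share of the reconstructed yield
#' (\code{sum eta_n V_n}) carried by nodes within \code{radius} of the true
#' target centre.
#'
#' @param eta_hat Reconstructed per-node yield.
#' @param mesh An \code{fmt_mesh} (nodal volume shares are used as weights).
#' @param true_center 3-vector, cm.
#' @param radius Inclusion radius, cm.
#' @return Fraction in [0, 1].
#' @export
recovered_mass_fraction <- function(eta_hat, mesh, true_center, radius = 0.5) {
  if (all(eta_hat == 0)) stop("metric error: all-zero reconstruction")
  mass <- eta_hat * mesh$nodal_volume
  d <- sqrt((mesh$node_coords[, 1] - true_center[1])^2 +
            (mesh$node_coords[, 2] - true_center[2])^2 +
            (mesh$node_coords[, 3] - true_center[3])^2)
  sum(mass[d <= radius]) / sum(mass)
}
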