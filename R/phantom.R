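#' Specification of the synthetic heterogeneous cylindrical phantom
#'
#' Describes a torso-like cylindrical volume (default radius 1.2 cm, height
#' 3 cm, axis along z) containing ellipsoidal organ-like regions with
#' distinct optical properties and a small cylindrical fluorescent target.
#'
#' @param radius_cm Cylinder radius, cm.
#' @param height_cm Cylinder height, cm (z spans \code{[0, height_cm]}).
#' @param target List with \code{center} (3-vector, cm), \code{radius} (cm),
#'   \code{height} (cm), \code{value} (fluorescence yield, arbitrary units).
#' @param organs List of organ regions; each a list with \code{label}
#'   (integer region id matching a row of \code{properties}), \code{center}
#'   (3-vector) and \code{semiaxes} (3-vector) of an axis-aligned ellipsoid.
#'   \code{default_organs()} supplies a heart/lung/liver arrangement.
#' @param edge_length_cm Characteristic mesh edge length away from the
#'   target, cm.
#' @param tau_ps Fluorophore lifetime, ps.
#' @param properties Region-to-optical-property table
#'   (see [tissue_optical_properties()]).
#' @param n_refractive Tissue refractive index.
#' @param refine_target Locally refine the mesh around the target so the
#'   nodal yield indicator resolves it (cell size \code{target$radius /
#'   refine_factor}).
#' @param refine_factor Cells across the target radius in the refined zone.
#' @return An object of class \code{fmt_phantom_spec}.
#' @export
phantom_spec <- function(radius_cm = 1.2, height_cm = 3,
                         target = list(center = c(-0.31, -0.02, 1.93),
                                       radius = 0.1, height = 0.2, value = 1),
                         organs = default_organs(),
                         edge_length_cm = 0.24, tau_ps = 560,
                         properties = tissue_optical_properties(),
                         n_refractive = 1.37,
                         refine_target = TRUE, refine_factor = 2.5) {
  stopifnot(radius_cm > 0, height_cm > 0, edge_length_cm > 0, tau_ps > 0)
  tg <- target
  if (is.null(tg$center) || length(tg$center) != 3 ||
      is.null(tg$radius) || is.null(tg$height) || is.null(tg$value)) {
    stop("geometry error: target needs center, radius, height, value")
  }
  # target must lie strictly inside the cylinder
  d0 <- sqrt(sum(tg$center[1:2]^2))
  if (d0 + tg$radius >= radius_cm ||
      tg$center[3] - tg$height / 2 <= 0 ||
      tg$center[3] + tg$height / 2 >= height_cm) {
    stop("geometry error: target does not lie strictly inside the cylinder")
  }
  for (o in organs) {
    if (is.null(o$label) || is.null(o$center) || is.null(o$semiaxes)) {
      stop("geometry error: each organ needs label, center, semiaxes")
    }
    if (!(o$label %in% properties$region)) {
      stop("assembly error: organ label ", o$label,
           " has no optical properties")
    }
    if (organ_overlaps_target(o, tg)) {
      stop("geometry error: organ region overlaps the target definition")
    }
  }
  structure(
    list(radius_cm = radius_cm, height_cm = height_cm, target = tg,
         organs = organs, edge_length_cm = edge_length_cm, tau_ps = tau_ps,
         properties = properties, n_refractive = n_refractive,
         refine_target = isTRUE(refine_target), refine_factor = refine_factor),
    class = "fmt_phantom_spec"
  )
}

#' Default organ arrangement for the heterogeneous phantom
#'
#' Three axis-aligned ellipsoids labelled heart (1), lung (2) and liver (3),
#' placed inside the default cylinder and clear of the default target.
#' @return List of organ definitions for [phantom_spec()].
#' @export
default_organs <- function() {
  list(
    list(label = 1L, tissue = "heart",
         center = c(0.0, 0.35, 2.1), semiaxes = c(0.35, 0.30, 0.40)),
    list(label = 2L, tissue = "lung",
         center = c(0.45, -0.25, 2.0), semiaxes = c(0.40, 0.35, 0.60)),
    list(label = 3L, tissue = "liver",
         center = c(-0.10, 0.10, 0.90), semiaxes = c(0.70, 0.60, 0.70))
  )
}

# Conservative overlap test: any probe point of the target cylinder inside
# the organ ellipsoid counts as overlap.
organ_overlaps_target <- function(organ, tg) {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- rbind(
    tg$center,
    t(vapply(ang, function(a) tg$center + c(tg$radius * cos(a),
                                            tg$radius * sin(a), 0),
             numeric(3)))
  )
  pts <- rbind(pts + rep(c(0, 0, tg$height / 2), each = nrow(pts)),
               pts - rep(c(0, 0, tg$height / 2), each = nrow(pts)),
               pts)
  u <- sweep(pts, 2, organ$center)
  inside <- rowSums(sweep(u, 2, organ$semiaxes, "/")^2) <= 1
  any(inside)
}

# Merge a coarse grid with a priority fine grid: all fine points (and `keep`
# points) survive; coarse points are dropped when closer than min_sep to a
# surviving point. `period` enables circular (angular) merging.
merge_grid <- function(base, fine, min_sep, keep = numeric(0), period = NULL) {
  pri <- sort(unique(c(fine, keep)))
  out <- pri
  for (b in sort(unique(base))) {
    d <- abs(out - b)
    if (!is.null(period)) d <- pmin(d, period - d)
    if (!length(out) || min(d) >= min_sep) out <- sort(c(out, b))
  }
  out
}

#' Build the heterogeneous cylindrical phantom
#'
#' Generates a tetrahedral mesh of the cylinder (tensor-product rings x
#' azimuths x layers; prisms split into three tetrahedra with a
#' sorted-index rule that keeps the mesh conforming), assigns organ region
#' labels by element centroid, and builds the per-node fluorescence yield
#' map: nodes inside the target cylinder carry \code{target$value}, all
#' others 0. With \code{refine_target} the grid is locally refined around
#' the target so the nodal indicator carries the target's volume.
#'
#' @param spec An [phantom_spec()] object.
#' @return List with \code{mesh} (\code{fmt_mesh}), \code{props}
#'   (\code{fmt_properties}), \code{fluor} (list \code{eta} per node,
#'   \code{tau} ps), and \code{spec}.
#' @export
build_cylindrical_phantom <- function(spec) {
  if (!inherits(spec, "fmt_phantom_spec")) {
    spec <- do.call(phantom_spec, as.list(spec))
  }
  R <- spec$radius_cm
  H <- spec$height_cm
  h <- spec$edge_length_cm
  tg <- spec$target

  nr <- max(2L, round(R / h))
  rings <- seq(0, R, length.out = nr + 1)[-1]
  nz <- max(2L, round(H / h))
  zs <- seq(0, H, length.out = nz + 1)
  m <- 6L * max(2L, round(pi * R / (6 * h)))
  angles <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]

  if (spec$refine_target) {
    s <- tg$radius / spec$refine_factor
    d0 <- sqrt(sum(tg$center[1:2]^2))
    th0 <- atan2(tg$center[2], tg$center[1]) %% (2 * pi)
    r_lo <- max(s, d0 - tg$radius - s / 2)
    r_hi <- min(R - s / 2, d0 + tg$radius + s / 2)
    rings <- merge_grid(rings, seq(r_lo, r_hi, by = s),
                        min_sep = 0.5 * s, keep = R)
    if (d0 > tg$radius) {
      half <- asin(min(1, (tg$radius + s / 2) / d0))
      dth <- s / d0
      fine_ang <- (th0 + seq(-half, half, by = dth)) %% (2 * pi)
      angles <- merge_grid(angles, fine_ang, min_sep = 0.5 * dth,
                           period = 2 * pi)
    }
    zf <- seq(tg$center[3] - tg$height / 2 - s / 2,
              tg$center[3] + tg$height / 2 + s / 2, by = s)
    zs <- merge_grid(zs, zf[zf > 0 & zf < H], min_sep = 0.5 * s,
                     keep = c(0, H))
  }

  m <- length(angles)
  nr <- length(rings)
  nplane <- length(zs)

  # disk node layout: node 1 = centre, then ring-major, angle-minor
  disk_n <- 1L + nr * m
  disk_xy <- matrix(0, disk_n, 2)
  for (i in seq_len(nr)) {
    idx <- 1L + (i - 1L) * m + seq_len(m)
    disk_xy[idx, 1] <- rings[i] * cos(angles)
    disk_xy[idx, 2] <- rings[i] * sin(angles)
  }
  ring_idx <- function(i, j) 1L + (i - 1L) * m + ((j - 1L) %% m) + 1L

  tri <- vector("list", nr)
  tri[[1]] <- cbind(1L, ring_idx(1, seq_len(m)), ring_idx(1, seq_len(m) + 1L))
  for (i in seq_len(nr - 1)) {
    a <- ring_idx(i, seq_len(m));      b <- ring_idx(i + 1, seq_len(m))
    c2 <- ring_idx(i + 1, seq_len(m) + 1L); d <- ring_idx(i, seq_len(m) + 1L)
    tri[[i + 1]] <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  }
  tri <- do.call(rbind, tri)
  # sort disk indices ascending per triangle: the prism split below then
  # chooses quad diagonals consistently across neighbouring prisms
  tri <- t(apply(tri, 1, sort))

  nodes <- cbind(disk_xy[rep(seq_len(disk_n), nplane), , drop = FALSE],
                 rep(zs, each = disk_n))

  nt <- nrow(tri)
  lay <- nplane - 1L
  a0 <- rep(tri[, 1], lay) + disk_n * rep(seq_len(lay) - 1L, each = nt)
  b0 <- rep(tri[, 2], lay) + disk_n * rep(seq_len(lay) - 1L, each = nt)
  c0 <- rep(tri[, 3], lay) + disk_n * rep(seq_len(lay) - 1L, each = nt)
  a1 <- a0 + disk_n; b1 <- b0 + disk_n; c1 <- c0 + disk_n
  conn <- rbind(cbind(a0, b0, c0, c1),
                cbind(a0, b0, c1, b1),
                cbind(a0, b1, c1, a1))

  mesh0 <- list(node_coords = nodes, tet_conn = conn)
  cent <- (nodes[conn[, 1], ] + nodes[conn[, 2], ] +
           nodes[conn[, 3], ] + nodes[conn[, 4], ]) / 4
  labels <- rep(0L, nrow(conn))
  for (o in spec$organs) {
    u <- sweep(cent, 2, o$center)
    inside <- rowSums(sweep(u, 2, o$semiaxes, "/")^2) <= 1
    labels[inside & labels == 0L] <- as.integer(o$label)
  }

  mesh <- fmt_mesh(nodes, conn, labels)
  props <- property_field(spec$properties, n_refractive = spec$n_refractive)

  dxy <- sqrt((mesh$node_coords[, 1] - tg$center[1])^2 +
              (mesh$node_coords[, 2] - tg$center[2])^2)
  inside <- dxy <= tg$radius + 1e-12 &
    abs(mesh$node_coords[, 3] - tg$center[3]) <= tg$height / 2 + 1e-12
  eta <- ifelse(inside, tg$value, 0)

  list(mesh = mesh,
       props = props,
       fluor = list(eta = eta, tau = spec$tau_ps),
       spec = spec)
}
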