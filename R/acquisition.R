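#' Rotation-stage projection geometry
#'
#' Describes the free-space acquisition: the source/detector frame rotates
#' about the z axis in fixed angular increments; for each excitation source
#' the detectors opposite it within an angular field of view and a z band
#' are used.
#'
#' @param n_projections Number of projections (default 6).
#' @param increment_deg Angular increment between projections, degrees
#'   (default 60; \code{n_projections * increment_deg} must equal 360).
#' @param fov_deg Detection field of view centred on the source antipode,
#'   degrees in (0, 360].
#' @param source_height_cm Source height on z, cm.
#' @param detector_zband_cm Detector half-band about the source height, cm.
#' @param detectors_per_projection Target detector count per projection;
#'   boundary candidates are deterministically subsampled to this density
#'   (NULL keeps all candidates).
#' @return Object of class \code{fmt_geometry}.
#' @export
projection_geometry <- function(n_projections = 6, increment_deg = 60,
                                fov_deg = 120, source_height_cm = 1.93,
                                detector_zband_cm = 0.75,
                                detectors_per_projection = 60) {
  if (abs(n_projections * increment_deg - 360) > 1e-9) {
    stop("configuration error: n_projections x increment_deg must be 360")
  }
  if (fov_deg <= 0 || fov_deg > 360) {
    stop("configuration error: fov_deg must lie in (0, 360]")
  }
  structure(
    list(n_projections = as.integer(n_projections),
         increment_deg = increment_deg, fov_deg = fov_deg,
         source_height_cm = source_height_cm,
         detector_zband_cm = detector_zband_cm,
         detectors_per_projection = detectors_per_projection),
    class = "fmt_geometry"
  )
}

# smallest absolute angular distance in degrees
ang_dist_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Place excitation sources around the boundary
#'
#' One surface illumination point per projection, at azimuth
#' \code{i * increment_deg} (i = 0, 1, ...) on the boundary at the source
#' height. The point is taken on the boundary surface nearest the requested
#' azimuth/height.
#'
#' @param geometry An [projection_geometry()].
#' @param mesh An \code{fmt_mesh}.
#' @return List of 3-vector surface points, one per projection.
#' @export
place_sources <- function(geometry, mesh) {
  bn <- boundary_nodes(mesh)
  bc <- mesh$node_coords[bn, , drop = FALSE]
  lapply(seq_len(geometry$n_projections) - 1L, function(i) {
    az <- (i * geometry$increment_deg) %% 360
    node_az <- atan2(bc[, 2], bc[, 1]) * 180 / pi
    score <- ang_dist_deg(node_az, az)^2 +
      (50 * (bc[, 3] - geometry$source_height_cm))^2
    # lateral-surface guard: prefer nodes away from the axis
    r <- sqrt(bc[, 1]^2 + bc[, 2]^2)
    score[r < 0.5 * max(r)] <- Inf
    if (!any(is.finite(score))) {
      stop("placement error: no boundary point near azimuth ", az)
    }
    bc[which.min(score), ]
  })
}

#' Select detector nodes opposite a source
#'
#' Boundary nodes whose azimuth lies within half the field of view of the
#' source's antipodal azimuth and whose height lies within the z band,
#' deterministically subsampled to the requested density.
#'
#' @param mesh An \code{fmt_mesh}.
#' @param source_point 3-vector surface point of the source.
#' @param fov_deg Field of view, degrees.
#' @param zband_cm Half-width of the detector z band, cm.
#' @param density Maximum detector count (NULL = all candidates).
#' @return Integer vector of boundary node indices (deterministic order).
#' @export
select_detectors <- function(mesh, source_point, fov_deg = 120,
                             zband_cm = 0.75, density = NULL) {
  bn <- boundary_nodes(mesh)
  bc <- mesh$node_coords[bn, , drop = FALSE]
  src_az <- atan2(source_point[2], source_point[1]) * 180 / pi
  antipode <- (src_az + 180) %% 360
  node_az <- atan2(bc[, 2], bc[, 1]) * 180 / pi
  r <- sqrt(bc[, 1]^2 + bc[, 2]^2)
  ok <- ang_dist_deg(node_az, antipode) <= fov_deg / 2 + 1e-9 &
    abs(bc[, 3] - source_point[3]) <= zband_cm + 1e-9 &
    r >= 0.5 * max(r)  # lateral surface only
  cand <- bn[ok]
  if (!length(cand)) stop("geometry error: empty detector selection")
  ord <- order(round(node_az[ok], 6), bc[ok, 3], cand)
  cand <- cand[ord]
  if (!is.null(density) && length(cand) > density) {
    keep <- unique(round(seq(1, length(cand), length.out = density)))
    cand <- cand[keep]
  }
  cand
}

#' Build the full acquisition layout on a mesh
#'
#' Places sources, selects each projection's detectors, and anchors both to
#' mesh nodes one transport mean free path inside the surface. Duplicate
#' detector anchors within a projection are dropped with a warning.
#'
#' @param mesh An \code{fmt_mesh}.
#' @param props An \code{fmt_properties}.
#' @param geometry An [projection_geometry()].
#' @return List of projections; each has \code{source} (\code{fmt_source}),
#'   \code{det_nodes} (boundary nodes), \code{det_anchors} (snapped
#'   interior anchor nodes, deduplicated).
#' @export
build_acquisition <- function(mesh, props, geometry) {
  pts <- place_sources(geometry, mesh)
  lapply(pts, function(p) {
    src <- point_source_vector(mesh, p, props)
    det <- select_detectors(mesh, p, geometry$fov_deg,
                            geometry$detector_zband_cm,
                            geometry$detectors_per_projection)
    anchors <- vapply(det, function(dn) {
      point_source_vector(mesh, mesh$node_coords[dn, ], props)$node
    }, integer(1))
    dup <- duplicated(anchors)
    if (any(dup)) {
      warning("duplicate detector anchor nodes deduplicated (",
              sum(dup), ")")
    }
    list(source = src, det_nodes = det[!dup], det_anchors = anchors[!dup])
  })
}
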