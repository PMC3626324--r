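#' Diffusion coefficient from absorption and reduced scattering
#'
#' Computes the photon diffusion coefficient
#' \eqn{D = 1 / (3 (\mu_a + \mu_s'))} used by the diffusion approximation of
#' light transport in scattering-dominated tissue.
#'
#' @param mu_a Absorption coefficient, 1/cm. Must be \code{>= 0}.
#' @param mu_s_prime Reduced scattering coefficient, 1/cm. Must be \code{> 0}.
#' @return Diffusion coefficient in cm. Vectorised over both arguments.
#' @examples
#' diffusion_coefficient(0.156, 9.0)  # heart tissue
#' diffusion_coefficient(0.1, 10)    # background tissue
#' @export
diffusion_coefficient <- function(mu_a, mu_s_prime) {
  if (any(!is.finite(mu_a)) || any(mu_a < 0)) {
    stop("invalid optical property: mu_a must be finite and >= 0")
  }
  if (any(!is.finite(mu_s_prime)) || any(mu_s_prime <= 0)) {
    stop("invalid optical property: mu_s_prime must be finite and > 0")
  }
  1 / (3 * (mu_a + mu_s_prime))
}

#' Reference tissue optical properties
#'
#' Absorption and reduced scattering coefficients for the heterogeneous
#' phantom regions (heart, lung, liver and a homogeneous background),
#' typical of murine tissue in the near infrared.
#'
#' @return A data frame with columns \code{region} (label), \code{tissue},
#'   \code{mu_a} (1/cm), \code{mu_s_prime} (1/cm).
#' @export
tissue_optical_properties <- function() {
  data.frame(
    region = c(0L, 1L, 2L, 3L),
    tissue = c("background", "heart", "lung", "liver"),
    mu_a = c(0.1, 0.156, 0.516, 0.935),
    mu_s_prime = c(10, 9.0, 21.2, 6.4),
    stringsAsFactors = FALSE
  )
}

#' Robin boundary mismatch coefficient from refractive index
#'
#' The boundary condition \eqn{\Phi + 2 q D \partial\Phi/\partial n = 0}
#' carries a coefficient \eqn{q} accounting for the refractive-index mismatch
#' at the tissue--air interface. This uses the standard effective-reflectance
#' parameterisation \eqn{q = (1 + R_{eff}) / (1 - R_{eff})} with
#' \eqn{R_{eff} = -1.440 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n}.
#'
#' @param n_refractive Tissue refractive index (default 1.37).
#' @return Dimensionless boundary coefficient \code{q}.
#' @export
boundary_mismatch_coefficient <- function(n_refractive = 1.37) {
  if (!is.finite(n_refractive) || n_refractive <= 0) {
    stop("invalid optical property: refractive index must be > 0")
  }
  r_eff <- -1.440 / n_refractive^2 + 0.710 / n_refractive +
    0.668 + 0.0636 * n_refractive
  (1 + r_eff) / (1 - r_eff)
}

# vacuum light speed in cm/ps
.C_VACUUM <- 0.0299792458

#' Per-region optical property field
#'
#' Bundles per-region absorption/scattering, the derived diffusion
#' coefficient, the boundary mismatch coefficient and the in-medium light
#' speed. Identical properties are used at the excitation and emission
#' wavelengths.
#'
#' @param regions Data frame with columns \code{region}, \code{mu_a},
#'   \code{mu_s_prime} (see [tissue_optical_properties()]).
#' @param n_refractive Tissue refractive index; sets \code{c = c0/n} and the
#'   boundary coefficient \code{q}.
#' @param q Optional explicit boundary coefficient overriding the value
#'   derived from \code{n_refractive}.
#' @return An object of class \code{fmt_properties} with elements
#'   \code{regions} (with derived column \code{D}, cm), \code{q}, \code{c}
#'   (cm/ps) and \code{n_refractive}.
#' @export
property_field <- function(regions = tissue_optical_properties(),
                           n_refractive = 1.37, q = NULL) {
  req <- c("region", "mu_a", "mu_s_prime")
  if (!all(req %in% names(regions))) {
    stop("invalid optical property table: need columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(regions$region)) {
    stop("invalid optical property table: duplicated region labels")
  }
  regions$D <- diffusion_coefficient(regions$mu_a, regions$mu_s_prime)
  if (is.null(q)) q <- boundary_mismatch_coefficient(n_refractive)
  if (!is.finite(q) || q <= 0) stop("invalid optical property: q must be > 0")
  structure(
    list(regions = regions, q = q, c = .C_VACUUM / n_refractive,
         n_refractive = n_refractive),
    class = "fmt_properties"
  )
}

#' @export
print.fmt_properties <- function(x, ...) {
  cat("<fmt_properties> q =", format(x$q, digits = 5),
      " c =", format(x$c, digits = 5), "cm/ps\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

# Look up per-element property values for a vector of region labels.
# Returns a data frame row-aligned with `labels`.
region_properties <- function(props, labels) {
  idx <- match(labels, props$regions$region)
  if (anyNA(idx)) {
    stop("assembly error: unmapped region label(s) ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  props$regions[idx, , drop = FALSE]
}
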