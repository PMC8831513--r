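#' Per-region optical properties at 665 nm
#'
#' A `region_optics` bundle holds the four transport parameters of one
#' tissue region: absorption coefficient `mu_a` (cm^-1), scattering
#' coefficient `mu_s` (cm^-1), scattering anisotropy `g` (mean cosine of the
#' single-scattering deflection), and refractive index `n`.
#'
#' @param mu_a absorption coefficient, cm^-1 (>= 0).
#' @param mu_s scattering coefficient, cm^-1 (>= 0).
#' @param g anisotropy factor, in (-1, 1).
#' @param n refractive index (>= 1).
#' @return object of class `region_optics`.
#' @export
region_optics <- function(mu_a, mu_s, g, n) {
  if (!is.finite(mu_a) || mu_a < 0) stop("mu_a must be >= 0")
  if (!is.finite(mu_s) || mu_s < 0) stop("mu_s must be >= 0")
  if (!is.finite(g) || abs(g) >= 1) stop("g must satisfy -1 < g < 1")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "region_optics")
}

#' @export
print.region_optics <- function(x, ...) {
  cat(sprintf("region_optics: mu_a = %g cm^-1, mu_s = %g cm^-1, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

# fixed (non-swept) parameters of the three-region model at 665 nm
.FIXED <- list(
  exterior = list(mu_a = 0.2, mu_s = 100, g = 0.9, n = 1.4),
  wall     = list(mu_s = 100, g = 0.9, n = 1.4),
  cavity   = list(g = 0.7, n = 1.33)
)

#' One cell of the optical-property sweep
#'
#' The sweeps vary three quantities: absorption at the abscess wall
#' (`mu_a_wall`, set by native tissue plus retained methylene blue),
#' scattering inside the cavity (`mu_s_cavity`, set by the instilled
#' Intralipid concentration), and absorption inside the cavity
#' (`mu_a_cavity`, residual methylene blue leakage). Everything else is
#' fixed: exterior tissue at (0.2, 100, 0.9, 1.4), wall scattering 100
#' cm^-1 with g 0.9 and n 1.4, cavity g 0.7 and n 1.33.
#'
#' @param mu_a_wall wall absorption coefficient, cm^-1.
#' @param mu_s_cavity intracavity scattering coefficient, cm^-1.
#' @param mu_a_cavity intracavity absorption coefficient, cm^-1.
#' @return object of class `property_cell`.
#' @export
property_cell <- function(mu_a_wall, mu_s_cavity, mu_a_cavity = 0) {
  for (v in c(mu_a_wall, mu_s_cavity, mu_a_cavity))
    if (!is.finite(v) || v < 0) stop("optical coefficients must be >= 0")
  if (mu_a_wall > 10 || mu_a_wall < 0.2)
    warning("mu_a_wall = ", mu_a_wall,
            " cm^-1 is outside the studied 0.2-10 cm^-1 range")
  if (mu_s_cavity > 100)
    warning("mu_s_cavity = ", mu_s_cavity,
            " cm^-1 is outside the studied 0-100 cm^-1 range")
  if (mu_a_cavity > 0.17)
    warning("mu_a_cavity = ", mu_a_cavity,
            " cm^-1 is outside the studied 0-0.17 cm^-1 range")
  structure(list(mu_a_wall = mu_a_wall, mu_s_cavity = mu_s_cavity,
                 mu_a_cavity = mu_a_cavity),
            class = "property_cell")
}

#' Assemble the label-to-optics map for a sweep cell
#'
#' @param cell a [property_cell()].
#' @return named list of three [region_optics()], in label order
#'   `exterior` (0), `wall` (1), `cavity` (2).
#' @export
assemble_properties <- function(cell) {
  stopifnot(inherits(cell, "property_cell"))
  f <- .FIXED
  list(
    exterior = region_optics(f$exterior$mu_a, f$exterior$mu_s,
                             f$exterior$g, f$exterior$n),
    wall = region_optics(cell$mu_a_wall, f$wall$mu_s, f$wall$g, f$wall$n),
    cavity = region_optics(cell$mu_a_cavity, cell$mu_s_cavity,
                           f$cavity$g, f$cavity$n)
  )
}

#' Methylene blue concentration to absorption coefficient
#'
#' Linear map at 665 nm anchored at 1 uM MB = 0.17 cm^-1 (so ~60 uM
#' corresponds to the highest wall absorption studied, 10 cm^-1). The
#' inverse is exact.
#'
#' @param concentration_um MB concentration, uM (>= 0).
#' @param mu_a absorption coefficient, cm^-1 (>= 0).
#' @return `mb_to_mua()` returns cm^-1; `mua_to_mb()` returns uM.
#' @export
mb_to_mua <- function(concentration_um) {
  if (any(!is.finite(concentration_um)) || any(concentration_um < 0))
    stop("MB concentration must be >= 0")
  0.17 * concentration_um
}

#' @rdname mb_to_mua
#' @export
mua_to_mb <- function(mu_a) {
  if (any(!is.finite(mu_a)) || any(mu_a < 0))
    stop("mu_a must be >= 0")
  mu_a / 0.17
}

#' Intralipid concentration to scattering coefficient
#'
#' Linear map at 665 nm anchored at 2.3% Intralipid = 100 cm^-1, the pairing
#' that defines the sweep axes (so 1%, the clinical instillation
#' concentration, maps to 43.48 cm^-1). Concentrations are percent lipid
#' (v/v). The inverse is exact.
#'
#' @param percent Intralipid concentration, % lipid (>= 0).
#' @param mu_s scattering coefficient, cm^-1 (>= 0).
#' @return `intralipid_to_mus()` returns cm^-1; `mus_to_intralipid()`
#'   returns %.
#' @export
intralipid_to_mus <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0))
    stop("Intralipid concentration must be >= 0")
  percent * (100 / 2.3)
}

#' @rdname intralipid_to_mus
#' @export
mus_to_intralipid <- function(mu_s) {
  if (any(!is.finite(mu_s)) || any(mu_s < 0))
    stop("mu_s must be >= 0")
  mu_s * (2.3 / 100)
}

#' Mie-based Intralipid scattering parameterization (cross-check model)
#'
#' Independent wavelength parameterization of Intralipid scattering after
#' van Staveren et al. (1991): for Intralipid-10%,
#' `mu_s = 0.016 * lambda^-2.4` mL^-1 L mm^-1 with `lambda` in um.
#' Expressed per percent lipid (1% lipid = 100 mL Intralipid-10% per litre)
#' this gives `mu_s(c, lambda) = 16 * lambda^-2.4 * c` cm^-1. It is provided
#' as a cross-check on the sweep-defining linear anchor in
#' [intralipid_to_mus()], not as the map the sweeps use; at 665 nm the two
#' agree to within about 2%.
#'
#' @param percent Intralipid concentration, % lipid.
#' @param mu_s scattering coefficient, cm^-1.
#' @param wavelength_nm wavelength, nm (default 665).
#' @return `intralipid_mus_mie()` returns cm^-1;
#'   `intralipid_from_mus_mie()` returns %.
#' @export
intralipid_mus_mie <- function(percent, wavelength_nm = 665) {
  if (any(!is.finite(percent)) || any(percent < 0))
    stop("Intralipid concentration must be >= 0")
  lambda_um <- wavelength_nm / 1000
  16 * lambda_um^(-2.4) * percent
}

#' @rdname intralipid_mus_mie
#' @export
intralipid_from_mus_mie <- function(mu_s, wavelength_nm = 665) {
  if (any(!is.finite(mu_s)) || any(mu_s < 0))
    stop("mu_s must be >= 0")
  lambda_um <- wavelength_nm / 1000
  mu_s / (16 * lambda_um^(-2.4))
}
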