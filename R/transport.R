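#' Light sources
#'
#' `fiber_source()` models the clinical flat-cleaved delivery fiber: 400-um
#' core (0.02 cm radius), numerical aperture 0.22, core index 1.46. Packets
#' start uniformly over the core face and within the acceptance cone of
#' half-angle `asin(NA / n_medium)` in the launch medium, uniform in solid
#' angle. `point_source()` is an isotropic point emitter used for
#' validation against closed-form solutions.
#'
#' @param position fiber tip / source position, cm.
#' @param direction fiber axis (need not be normalized).
#' @param radius core radius, cm.
#' @param na numerical aperture.
#' @param n_fiber fiber core refractive index.
#' @param power delivered (out-of-fiber) power, mW.
#' @return object of class `light_source`.
#' @export
fiber_source <- function(position, direction = c(0, 0, 1), radius = 0.02,
                         na = 0.22, n_fiber = 1.46, power = 1) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("fiber direction must be a nonzero vector")
  if (radius <= 0) stop("core radius must be > 0")
  if (na <= 0 || na >= n_fiber) stop("need 0 < NA < n_fiber")
  structure(list(type = "fiber", position = as.numeric(position),
                 direction = as.numeric(direction) / nrm, radius = radius,
                 na = na, n_fiber = n_fiber, power = power),
            class = "light_source")
}

#' @rdname fiber_source
#' @export
point_source <- function(position, power = 1) {
  structure(list(type = "point", position = as.numeric(position),
                 power = power),
            class = "light_source")
}

#' Henyey-Greenstein deflection-cosine sampling
#'
#' Inverse-CDF sample of the scattering deflection cosine: for `g != 0`,
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g u))^2) / (2 g)`; for
#' `g = 0`, `cos(theta) = 2u - 1` (isotropic). `E[cos(theta)] = g`.
#'
#' @param g anisotropy factor, `|g| < 1`.
#' @param u uniform variates in `[0, 1)`.
#' @return deflection cosines, same length as `u`.
#' @export
sample_hg <- function(g, u) sample_hg_cpp(g, as.numeric(u))

#' Unpolarized Fresnel reflectance at a refractive-index step
#'
#' Average of the s- and p-polarized reflectances; returns 1 beyond the
#' critical angle (total internal reflection). The transmitted direction
#' cosine follows Snell's law.
#'
#' @param n_i,n_t incident and transmitted refractive indices.
#' @param cos_i cosine of the angle of incidence, in `[0, 1]`.
#' @return list with `reflectance` and `cos_t` (transmitted cosine, 0 under
#'   total internal reflection).
#' @export
fresnel_reflectance <- function(n_i, n_t, cos_i) {
  if (n_i < 1 || n_t < 1) stop("refractive indices must be >= 1")
  if (any(cos_i < 0) || any(cos_i > 1)) stop("cos_i must lie in [0, 1]")
  fresnel_cpp(n_i, n_t, as.numeric(cos_i))
}

#' Sample photon launches from a source
#'
#' Draws launch positions and directions only (no transport); used to
#' verify the source model.
#'
#' @param source a [fiber_source()] or [point_source()].
#' @param n number of launches.
#' @param seed RNG seed.
#' @param n_medium refractive index of the launch medium (fiber acceptance
#'   cone is computed in the medium; default cavity water/Intralipid, 1.33).
#' @return data.frame with columns x, y, z, ux, uy, uz.
#' @export
sample_launch <- function(source, n, seed = 1L, n_medium = 1.33) {
  src <- source_to_list(source, n_medium)
  m <- mc_launch_cpp(src, as.integer(n), as.integer(seed))
  stats::setNames(as.data.frame(m), c("x", "y", "z", "ux", "uy", "uz"))
}

source_to_list <- function(source, n_medium) {
  stopifnot(inherits(source, "light_source"))
  if (source$type == "fiber")
    list(type = "fiber", position = source$position,
         direction = source$direction, radius = source$radius,
         na = source$na, n_medium = n_medium)
  else
    list(type = "point", position = source$position)
}

#' Simulate a fluence-rate map by voxel Monte Carlo
#'
#' Propagates weighted photon packets through the three-region voxel
#' geometry and tallies per-voxel fluence rate per unit delivered power
#' (cm^-2) with an expected-track-length estimator, which remains defined
#' where `mu_a = 0` (the cavity). Packets advance by scattering optical
#' depth with carry-over across voxel boundaries (3D DDA traversal);
#' absorption attenuates the weight continuously along each segment;
#' Fresnel reflection / Snell refraction is applied at any voxel face where
#' the refractive index changes; low-weight packets undergo Russian
#' roulette; packets leaving the grid are tallied as escaped. Deterministic
#' given `seed`: each packet uses an RNG substream keyed by (seed, packet
#' index), so results are independent of execution order.
#'
#' @param grid a [label_grid()], or for homogeneous validation runs any
#'   grid whose labels index `optics`.
#' @param optics list of [region_optics()] in label order (label 0 first),
#'   e.g. from [assemble_properties()].
#' @param source a [fiber_source()] (tip must lie in the cavity region) or
#'   [point_source()].
#' @param n_photons number of photon packets (default 1e5).
#' @param seed integer RNG seed.
#' @param w_min,p_survive Russian-roulette weight threshold and survival
#'   probability.
#' @return object of class `fluence_map`: per-voxel fluence rate per mW
#'   (`values`, cm^-2), `absorbed` and `escaped` weight fractions
#'   (summing to 1), photon count and seed provenance.
#' @export
simulate_fluence <- function(grid, optics, source, n_photons = 1e5,
                             seed = 1L, w_min = 1e-4, p_survive = 0.1) {
  stopifnot(is_label_grid(grid))
  n_photons <- as.integer(n_photons)
  if (is.na(n_photons) || n_photons < 1) stop("n_photons must be >= 1")
  if (inherits(optics, "region_optics")) optics <- list(optics)
  if (!all(vapply(optics, inherits, TRUE, "region_optics")))
    stop("`optics` must be a list of region_optics in label order")
  d <- dim(grid$labels)
  if (any(d == 0)) stop("zero-size grid")
  om <- do.call(rbind, lapply(optics, function(o)
    c(o$mu_a, o$mu_s, o$g, o$n)))
  if (max(grid$labels) + 1L > nrow(om))
    stop("labels reference regions missing from `optics`")

  pos <- source$position
  vox <- floor((pos - grid$origin) / grid$spacing + 0.5) + 1
  if (any(vox < 1) || any(vox > d))
    stop("source position lies outside the grid")
  lab_at <- grid$labels[matrix(as.integer(vox), 1)]
  if (source$type == "fiber" && lab_at != 2L && length(optics) >= 3L)
    stop("source placement error: fiber tip must lie inside the cavity region")
  n_medium <- om[lab_at + 1L, 4]

  res <- mc_simulate_cpp(as.vector(grid$labels), d, grid$spacing,
                         grid$origin, om, source_to_list(source, n_medium),
                         n_photons, as.integer(seed), w_min, p_survive)
  structure(list(values = array(res$fluence, d),
                 spacing = grid$spacing, origin = grid$origin,
                 n_photons = n_photons, seed = as.integer(seed),
                 absorbed = res$absorbed, escaped = res$escaped,
                 power_mw = 1,
                 source = list(type = source$type, position = pos)),
            class = "fluence_map")
}

#' Scale a per-mW fluence map to a delivered power
#'
#' Fluence rate is linear in delivered power, so one 1-mW simulation per
#' geometry/optics cell serves all candidate powers.
#'
#' @param map a `fluence_map`.
#' @param power_mw delivered power, mW (>= 0).
#' @return a `fluence_map` whose values are in mW/cm^2 at `power_mw`.
#' @export
scale_to_power <- function(map, power_mw) {
  stopifnot(inherits(map, "fluence_map"))
  if (!is.finite(power_mw) || power_mw < 0)
    stop("power must be >= 0 mW")
  map$values <- map$values * power_mw
  map$power_mw <- map$power_mw * power_mw
  map
}

#' @export
print.fluence_map <- function(x, ...) {
  cat("fluence_map: ", paste(dim(x$values), collapse = " x "),
      " voxels, N = ", format(x$n_photons, big.mark = ","),
      ", seed ", x$seed, "\n  absorbed ", signif(x$absorbed, 6),
      ", escaped ", signif(x$escaped, 6), ", power ", x$power_mw, " mW\n",
      sep = "")
  invisible(x)
}
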