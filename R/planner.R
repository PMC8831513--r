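#' Treatment-plan dose targets
#'
#' The planning constraints: achieve a fluence rate of at least `target`
#' (4 mW/cm^2) over at least `coverage` (95%) of the cavity-facing wall
#' area, while no more than `hotspot_fraction` (5%) of the wall receives
#' `hotspot_limit` (400 mW/cm^2) or more, with at most `max_power`
#' (2000 mW) of out-of-fiber power. A geometry/optics cell is *eligible*
#' when both dose constraints are met strictly below `max_power`.
#'
#' @param target coverage fluence-rate target, mW/cm^2.
#' @param coverage wall area fraction that must reach `target`, in (0,1).
#' @param hotspot_limit thermal-safety fluence-rate limit, mW/cm^2.
#' @param hotspot_fraction maximum wall area fraction at or above
#'   `hotspot_limit`, in (0,1).
#' @param max_power laser power cap, mW.
#' @return object of class `dose_targets`.
#' @export
dose_targets <- function(target = 4, coverage = 0.95,
                         hotspot_limit = 400, hotspot_fraction = 0.05,
                         max_power = 2000) {
  if (!(coverage > 0 && coverage < 1)) stop("coverage must be in (0, 1)")
  if (!(hotspot_fraction > 0 && hotspot_fraction < 1))
    stop("hotspot_fraction must be in (0, 1)")
  if (!(target > 0 && hotspot_limit > target))
    stop("need 0 < target < hotspot_limit")
  if (max_power <= 0) stop("max_power must be > 0")
  structure(list(target = target, coverage = coverage,
                 hotspot_limit = hotspot_limit,
                 hotspot_fraction = hotspot_fraction,
                 max_power = max_power),
            class = "dose_targets")
}

#' Per-mW fluence distribution on the cavity wall
#'
#' Pairs the fluence-rate-per-mW value at each wall-surface voxel with that
#' voxel's representative area. All planning quantities (threshold power,
#' hotspot check, eligibility) are area-weighted statistics of this
#' distribution.
#'
#' @param map a `fluence_map` from [simulate_fluence()].
#' @param surface a [wall_surface()] from the same grid.
#' @return object of class `wall_fluence`: list with `phi` (cm^-2 per mW)
#'   and `area` (cm^2).
#' @export
wall_distribution <- function(map, surface) {
  stopifnot(inherits(map, "fluence_map"), inherits(surface, "wall_surface"))
  if (!identical(dim(map$values), as.integer(surface$grid_dim)) &&
      !identical(dim(map$values), surface$grid_dim))
    stop("fluence map and wall surface come from different grids")
  if (length(surface$index) == 0L) stop("empty wall surface")
  phi <- map$values[surface$index] / map$power_mw
  structure(list(phi = as.numeric(phi), area = surface$area),
            class = "wall_fluence")
}

#' @rdname wall_distribution
#' @param phi per-mW fluence values, cm^-2.
#' @param area matching areas, cm^2 (recycled if scalar).
#' @export
wall_fluence <- function(phi, area = 1) {
  phi <- as.numeric(phi)
  if (length(phi) == 0L) stop("empty wall fluence distribution")
  if (any(phi < 0)) stop("fluence values must be >= 0")
  area <- rep_len(as.numeric(area), length(phi))
  structure(list(phi = phi, area = area), class = "wall_fluence")
}

# Area-weighted order statistics that pin the planning conventions:
#  q_low:  largest sample value v with area-fraction(phi < v) <= alpha
#          (the coverage quantile; alpha = 1 - coverage)
#  q_high: largest sample value v with area-fraction(phi >= v) > alpha
#          (the hotspot quantile; alpha = hotspot_fraction)
# Both are realized sample values, so coverage computed from them agrees
# exactly with direct area counting.
wall_quantiles <- function(dist, alpha_low, alpha_high) {
  o <- order(dist$phi)
  v <- dist$phi[o]
  a <- dist$area[o] / sum(dist$area)
  below <- c(0, cumsum(a)[-length(a)])   # area fraction strictly below v[i]
  # ties: fraction strictly below a value is that of its first occurrence
  first <- !duplicated(v)
  below <- rep(below[first], times = tabulate(match(v, v[first])))
  tol <- 1e-12
  q_low <- max(v[below <= alpha_low + tol])
  ge <- 1 - below                         # area fraction with phi >= v[i]
  idx <- which(ge > alpha_high + tol)
  q_high <- if (length(idx)) max(v[idx]) else min(v)
  c(q_low = q_low, q_high = q_high)
}

#' Threshold optical power
#'
#' The minimum delivered power at which the coverage target is met:
#' `P_th = target / q`, where `q` is the area-weighted lower quantile of
#' the per-mW wall fluence at probability `1 - coverage` (the largest wall
#' value with no more than 5% of the wall area strictly below it). Because
#' fluence scales linearly with power, this is exactly the least power
#' whose covered area fraction reaches `coverage`; a brute-force power scan
#' returns the same value. If 5% of the wall receives no light at all
#' (`q = 0`), the threshold is infinite and the cell cannot be made
#' eligible at any power.
#'
#' @param dist a [wall_fluence()] distribution.
#' @param targets a [dose_targets()].
#' @return threshold power, mW (possibly `Inf`).
#' @export
threshold_power <- function(dist, targets = dose_targets()) {
  stopifnot(inherits(dist, "wall_fluence"), inherits(targets, "dose_targets"))
  q <- wall_quantiles(dist, 1 - targets$coverage, targets$hotspot_fraction)
  if (q[["q_low"]] <= 0) return(Inf)
  targets$target / q[["q_low"]]
}

#' Hotspot (thermal-safety) check at a given power
#'
#' TRUE when the wall area fraction receiving at least `hotspot_limit`
#' (closed inequality, ">= 400 mW/cm^2") does not exceed
#' `hotspot_fraction`. Computed by direct area counting.
#'
#' @param dist a [wall_fluence()] distribution (per mW).
#' @param targets a [dose_targets()].
#' @param power delivered power, mW (>= 0).
#' @return logical.
#' @export
hotspot_feasible <- function(dist, targets = dose_targets(), power) {
  stopifnot(inherits(dist, "wall_fluence"), inherits(targets, "dose_targets"))
  if (!is.finite(power) || power < 0) {
    if (is.infinite(power) && power > 0) return(FALSE)
    stop("power must be >= 0")
  }
  thr <- targets$hotspot_limit * (1 - 1e-12)  # round-off-safe closed bound
  hot <- sum(dist$area[power * dist$phi >= thr])
  hot / sum(dist$area) <= targets$hotspot_fraction + 1e-12
}

#' Eligibility of one geometry/optics cell
#'
#' A cell is eligible when the threshold power is strictly below the laser
#' cap ("less than 2000 mW") and the hotspot constraint holds at the
#' threshold power. Equivalently, in closed form: `target/q05 < max_power`
#' and `q95/q05 < hotspot_limit/target` (= 100 at the defaults), where
#' `q05` is the coverage quantile and `q95` the hotspot quantile of the
#' per-mW wall fluence; both routes agree by construction.
#'
#' @param dist a [wall_fluence()] distribution (per mW).
#' @param targets a [dose_targets()].
#' @return list with `p_threshold` (mW), `hotspot_ok` (at the threshold
#'   power), `eligible`, and the quantiles `q05`, `q95` (cm^-2 per mW).
#' @export
eligibility <- function(dist, targets = dose_targets()) {
  stopifnot(inherits(dist, "wall_fluence"), inherits(targets, "dose_targets"))
  q <- wall_quantiles(dist, 1 - targets$coverage, targets$hotspot_fraction)
  p_th <- if (q[["q_low"]] <= 0) Inf else targets$target / q[["q_low"]]
  hot_ok <- is.finite(p_th) && hotspot_feasible(dist, targets, p_th)
  list(p_threshold = p_th,
       hotspot_ok = hot_ok,
       eligible = is.finite(p_th) && p_th < targets$max_power && hot_ok,
       q05 = unname(q[["q_low"]]), q95 = unname(q[["q_high"]]))
}

#' Optimal Intralipid concentration at fixed wall absorption
#'
#' Given plan rows simulated over the Intralipid grid at one geometry and
#' one wall absorption, returns the simulated concentration minimizing the
#' threshold power — no interpolation between simulated concentrations.
#' Ineligible rows are excluded unless all rows are ineligible, in which
#' case the minimum-threshold row is still reported (flagged ineligible)
#' so sweep tables stay rectangular. Ties break toward the lowest
#' concentration.
#'
#' @param plans data.frame with columns `intralipid_pct`, `p_threshold`,
#'   `eligible` (one row per simulated concentration).
#' @return the selected row of `plans`.
#' @export
optimal_intralipid <- function(plans) {
  if (NROW(plans) == 0L) stop("empty plan list")
  stopifnot(all(c("intralipid_pct", "p_threshold", "eligible") %in%
                  names(plans)))
  cand <- if (any(plans$eligible)) plans[plans$eligible, , drop = FALSE]
          else plans
  o <- order(cand$p_threshold, cand$intralipid_pct)
  cand[o[1], , drop = FALSE]
}

#' Uniform-dose comparator plan
#'
#' The clinical-protocol comparator: Intralipid fixed at the grid
#' concentration nearest 1% (the trial instillation concentration), power
#' optimized. Serves as the baseline against which patient-specific
#' optimization of the Intralipid concentration is compared.
#'
#' @param plans data.frame as in [optimal_intralipid()].
#' @param concentration fixed concentration, % (default 1).
#' @param tol maximum allowed distance (%) between `concentration` and the
#'   nearest grid concentration.
#' @return the selected row of `plans`.
#' @export
uniform_dose_plan <- function(plans, concentration = 1, tol = 0.5) {
  if (NROW(plans) == 0L) stop("empty plan list")
  d <- abs(plans$intralipid_pct - concentration)
  if (min(d) > tol)
    stop("no simulated Intralipid concentration within ", tol, "% of ",
         concentration, "%")
  plans[which.min(d), , drop = FALSE]
}
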