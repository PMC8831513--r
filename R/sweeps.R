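# Sweeps over optical-property grids: one MC simulation per
# (geometry, mu_a_wall, mu_s_cavity[, mu_a_cavity]) cell, then treatment
# planning on the resulting wall distributions.

# Stable per-task seed in [1, 2^31-2], derived from the master seed and a
# task key string, so adding grid cells never perturbs existing cells.
task_seed <- function(master_seed, key) {
  s <- paste0(master_seed, "|", key)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1)
}

#' Area fraction of the wall at or above the coverage target
#'
#' Direct area counting of the covered fraction at a given power; the
#' counting route that pins the percentile conventions used by
#' [threshold_power()] and [hotspot_feasible()].
#'
#' @param dist a [wall_fluence()] distribution (per mW).
#' @param targets a [dose_targets()].
#' @param power delivered power, mW.
#' @return covered area fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(dist, targets = dose_targets(), power) {
  stopifnot(inherits(dist, "wall_fluence"))
  # 1e-12 relative slack so P_th * q05 == target holds through floating
  # round-off (P_th is computed as target / q05)
  thr <- targets$target * (1 - 1e-12)
  sum(dist$area[power * dist$phi >= thr]) / sum(dist$area)
}

# normalize the `geometries` argument to a named list of label_grids
as_geometry_list <- function(geometries) {
  if (is_label_grid(geometries)) geometries <- list(geometries)
  stopifnot(length(geometries) >= 1,
            all(vapply(geometries, is_label_grid, TRUE)))
  if (is.null(names(geometries)) || any(names(geometries) == ""))
    names(geometries) <- sprintf("geom%02d", seq_along(geometries))
  geometries
}

# simulate one sweep cell (with optional NIfTI map caching for resumable
# sweeps), returning the plan row for that cell
simulate_cell <- function(grid, surface, source, cell, n_photons, cell_seed,
                          targets, geometry_id, cache_dir = NULL, key = NULL) {
  map <- NULL
  if (!is.null(cache_dir) && !is.null(key)) {
    f <- file.path(cache_dir, paste0(key, ".nii"))
    if (file.exists(f) && file.exists(paste0(f, ".json"))) {
      cached <- load_fluence(f)
      if (identical(as.integer(cached$n_photons), as.integer(n_photons)) &&
          identical(as.integer(cached$seed), as.integer(cell_seed)))
        map <- cached
    }
  }
  if (is.null(map)) {
    map <- simulate_fluence(grid, assemble_properties(cell), source,
                            n_photons = n_photons, seed = cell_seed)
    if (!is.null(cache_dir) && !is.null(key)) {
      dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
      save_fluence(map, file.path(cache_dir, paste0(key, ".nii")))
    }
  }
  dist <- wall_distribution(map, surface)
  el <- eligibility(dist, targets)
  list(
    row = data.frame(
      geometry = geometry_id,
      mu_a_wall = cell$mu_a_wall,
      mu_s_cavity = cell$mu_s_cavity,
      mu_a_cavity = cell$mu_a_cavity,
      intralipid_pct = mus_to_intralipid(cell$mu_s_cavity),
      p_threshold = el$p_threshold,
      q05 = el$q05, q95 = el$q95,
      hotspot_ok = el$hotspot_ok,
      eligible = el$eligible,
      absorbed = map$absorbed, escaped = map$escaped,
      n_photons = n_photons, seed = cell_seed,
      stringsAsFactors = FALSE),
    dist = dist)
}

#' Case-1 sweep: wall absorption x intracavity Intralipid
#'
#' Runs one Monte Carlo simulation per (geometry, `mu_a_wall`,
#' `mu_s_cavity`) combination with zero intracavity absorption, plans each
#' cell, and derives per-(geometry, `mu_a_wall`) optimized-Intralipid and
#' uniform-dose (1% Intralipid, power-optimized) treatment plans, plus
#' eligibility fractions across geometries. The fiber tip is placed at the
#' cavity centroid, as in the clinical procedure.
#'
#' @param geometries a [label_grid()] or (named) list of them.
#' @param mu_a_wall explicit wall absorption values, cm^-1.
#' @param mu_s_cavity explicit intracavity scattering values, cm^-1.
#' @param targets a [dose_targets()].
#' @param n_photons packets per simulation.
#' @param seed master seed; per-cell seeds are derived by stable hashing of
#'   the task key.
#' @param cache_dir optional directory for per-cell fluence maps (NIfTI +
#'   sidecar); cells whose map is already present are not re-simulated.
#' @return object of class `sweep_case1`: list with `cells` (one plan row
#'   per simulation), `plans` (optimized and uniform strategies per
#'   geometry and `mu_a_wall`), and `eligibility` (fractions per strategy
#'   and `mu_a_wall` across geometries).
#' @export
run_sweep_case1 <- function(geometries, mu_a_wall, mu_s_cavity,
                            targets = dose_targets(), n_photons = 1e5,
                            seed = 1L, cache_dir = NULL) {
  geometries <- as_geometry_list(geometries)
  stopifnot(length(mu_a_wall) >= 1, length(mu_s_cavity) >= 1)
  cells <- list()
  for (gid in names(geometries)) {
    grid <- geometries[[gid]]
    surface <- wall_surface(grid)
    source <- fiber_source(cavity_center_of_mass(grid)$point)
    for (maw in mu_a_wall) {
      for (msc in mu_s_cavity) {
        key <- sprintf("%s_maw%g_msc%g_mac0", gid, maw, msc)
        res <- simulate_cell(grid, surface, source,
                             property_cell(maw, msc, 0),
                             n_photons, task_seed(seed, key), targets,
                             gid, cache_dir, key)
        cells[[key]] <- res$row
      }
    }
  }
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  plans <- list()
  for (gid in names(geometries)) {
    for (maw in mu_a_wall) {
      sub <- cells[cells$geometry == gid & cells$mu_a_wall == maw, ,
                   drop = FALSE]
      opt <- optimal_intralipid(sub)
      uni <- uniform_dose_plan(sub)
      opt$strategy <- "optimized"
      uni$strategy <- "uniform"
      plans[[paste(gid, maw)]] <- rbind(opt, uni)
    }
  }
  plans <- do.call(rbind, c(plans, list(make.row.names = FALSE)))
  elig <- stats::aggregate(eligible ~ strategy + mu_a_wall, data = plans,
                           FUN = mean)
  names(elig)[names(elig) == "eligible"] <- "eligible_fraction"
  structure(list(cells = cells, plans = plans, eligibility = elig,
                 targets = targets, seed = seed, n_photons = n_photons),
            class = "sweep_case1")
}

#' Case-2 sweep: absorption inside the cavity
#'
#' Extends the case-1 grid with intracavity absorption (`mu_a_cavity`,
#' residual methylene blue) and evaluates three planning modes per
#' (geometry, `mu_a_wall`, `mu_a_cavity`) cell:
#'
#' * `fixed-plan` — power and Intralipid frozen at the values planned for
#'   `mu_a_cavity = 0`; eligibility is whether that frozen plan still meets
#'   both dose constraints under the actual intracavity absorption.
#' * `power-only` — Intralipid frozen at the `mu_a_cavity = 0` optimum,
#'   power re-optimized.
#' * `full` — both power and Intralipid re-optimized.
#'
#' `mu_a_cavity` must contain 0, which provides the baseline plans.
#'
#' @inheritParams run_sweep_case1
#' @param mu_a_cavity explicit intracavity absorption values, cm^-1; must
#'   include 0.
#' @param modes subset of `c("fixed-plan", "power-only", "full")`.
#' @return object of class `sweep_case2`: list with `cells` (every
#'   simulated cell), `modes` (one row per geometry, `mu_a_wall`,
#'   `mu_a_cavity`, mode), and `eligibility` (fractions across geometries).
#' @export
run_sweep_case2 <- function(geometries, mu_a_wall, mu_s_cavity, mu_a_cavity,
                            targets = dose_targets(), n_photons = 1e5,
                            seed = 1L,
                            modes = c("fixed-plan", "power-only", "full"),
                            cache_dir = NULL) {
  geometries <- as_geometry_list(geometries)
  bad <- setdiff(modes, c("fixed-plan", "power-only", "full"))
  if (length(bad)) stop("unknown planning mode: ", paste(bad, collapse = ", "))
  if (!any(mu_a_cavity == 0))
    stop("mu_a_cavity must include 0 (the baseline used to freeze plans)")
  cells <- list()
  dists <- list()
  for (gid in names(geometries)) {
    grid <- geometries[[gid]]
    surface <- wall_surface(grid)
    source <- fiber_source(cavity_center_of_mass(grid)$point)
    for (maw in mu_a_wall) {
      for (msc in mu_s_cavity) {
        for (mac in mu_a_cavity) {
          key <- sprintf("%s_maw%g_msc%g_mac%g", gid, maw, msc, mac)
          res <- simulate_cell(grid, surface, source,
                               property_cell(maw, msc, mac),
                               n_photons, task_seed(seed, key), targets,
                               gid, cache_dir, key)
          cells[[key]] <- res$row
          dists[[key]] <- res$dist
        }
      }
    }
  }
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))

  rows <- list()
  for (gid in names(geometries)) {
    for (maw in mu_a_wall) {
      base <- cells[cells$geometry == gid & cells$mu_a_wall == maw &
                      cells$mu_a_cavity == 0, , drop = FALSE]
      frozen <- optimal_intralipid(base)
      for (mac in mu_a_cavity) {
        sub <- cells[cells$geometry == gid & cells$mu_a_wall == maw &
                       cells$mu_a_cavity == mac, , drop = FALSE]
        for (mode in modes) {
          if (mode == "fixed-plan") {
            key <- sprintf("%s_maw%g_msc%g_mac%g", gid, maw,
                           frozen$mu_s_cavity, mac)
            d <- dists[[key]]
            p <- frozen$p_threshold
            ok <- is.finite(p) && p < targets$max_power &&
              coverage_fraction(d, targets, p) >= targets$coverage - 1e-12 &&
              hotspot_feasible(d, targets, p)
            sel <- data.frame(intralipid_pct = frozen$intralipid_pct,
                              power = p, eligible = ok)
          } else if (mode == "power-only") {
            row <- sub[sub$mu_s_cavity == frozen$mu_s_cavity, , drop = FALSE]
            sel <- data.frame(intralipid_pct = row$intralipid_pct,
                              power = row$p_threshold,
                              eligible = row$eligible)
          } else {  # full
            row <- optimal_intralipid(sub)
            sel <- data.frame(intralipid_pct = row$intralipid_pct,
                              power = row$p_threshold,
                              eligible = row$eligible)
          }
          rows[[paste(gid, maw, mac, mode)]] <-
            cbind(data.frame(geometry = gid, mu_a_wall = maw,
                             mu_a_cavity = mac, mode = mode,
                             stringsAsFactors = FALSE), sel)
        }
      }
    }
  }
  modes_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  elig <- stats::aggregate(eligible ~ mode + mu_a_wall + mu_a_cavity,
                           data = modes_tab, FUN = mean)
  names(elig)[names(elig) == "eligible"] <- "eligible_fraction"
  structure(list(cells = cells, modes = modes_tab, eligibility = elig,
                 targets = targets, seed = seed, n_photons = n_photons),
            class = "sweep_case2")
}
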