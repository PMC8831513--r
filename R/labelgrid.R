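#' Three-region voxel geometry
#'
#' A `label_grid` is the voxelized geometry all simulation and planning
#' functions operate on: a 3D integer array of region labels (0 = exterior
#' tissue, 1 = abscess wall, 2 = cavity interior) together with the physical
#' voxel spacing and the physical coordinate of the center of voxel
#' `(1,1,1)`. All lengths are in cm; anisotropic spacing is supported because
#' CT grids are anisotropic.
#'
#' @param labels 3D integer array with values in `{0, 1, 2}`.
#' @param spacing numeric length-3, voxel edge lengths in cm (all > 0).
#' @param origin numeric length-3, physical coordinate (cm) of the center of
#'   the first voxel. Defaults to `spacing / 2` (grid corner at 0).
#' @param check validate the separation invariant (no cavity voxel 6-adjacent
#'   to an exterior voxel) and cavity connectedness. Set `FALSE` only for
#'   grids known valid (e.g. just generated).
#' @return an object of class `label_grid`.
#' @export
label_grid <- function(labels, spacing, origin = spacing / 2, check = TRUE) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths (cm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite physical coordinate (cm)")
  vals <- sort(unique(as.vector(labels)))
  if (!all(vals %in% 0:2))
    stop("labels must take values in {0 = exterior, 1 = wall, 2 = cavity}")
  g <- structure(list(labels = labels, spacing = spacing, origin = origin),
                 class = "label_grid")
  if (check) validate_label_grid(g)
  g
}

#' @rdname label_grid
#' @param x object to test or validate.
#' @export
is_label_grid <- function(x) inherits(x, "label_grid")

#' @rdname label_grid
#' @export
validate_label_grid <- function(x) {
  stopifnot(is_label_grid(x))
  lab <- x$labels
  cav <- lab == 2L
  if (any(cav)) {
    # separation: every 6-neighbor of a cavity voxel is wall or cavity
    if (cavity_touches_exterior(lab))
      stop("invalid geometry: a cavity voxel is 6-adjacent to an exterior voxel")
    comp <- label_components6_cpp(as.vector(cav), dim(lab))
    if (max(comp) > 1L)
      stop("invalid geometry: cavity voxels form ",
           max(comp), " 6-connected components (must be 1)")
  }
  invisible(x)
}

# TRUE if any cavity voxel has an exterior 6-neighbor (or lies on the domain
# face, where the separation shell is absent by construction).
cavity_touches_exterior <- function(lab) {
  d <- dim(lab)
  cav <- lab == 2L
  if (!any(cav)) return(FALSE)
  idx <- which(cav, arr.ind = TRUE)
  if (any(idx[, 1] %in% c(1L, d[1])) || any(idx[, 2] %in% c(1L, d[2])) ||
      any(idx[, 3] %in% c(1L, d[3])))
    return(TRUE)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + s
      if (any(lab[nb] == 0L)) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.label_grid <- function(x, ...) {
  d <- dim(x$labels)
  n_cav <- sum(x$labels == 2L)
  n_wall <- sum(x$labels == 1L)
  vv <- prod(x$spacing)
  cat("label_grid: ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " cm\n", sep = "")
  cat("  cavity: ", n_cav, " voxels (", signif(n_cav * vv, 4), " cm^3), wall: ",
      n_wall, " voxels\n", sep = "")
  invisible(x)
}

# physical coordinates (cm) of the centers of the voxels in `idx`
# (n x 3 1-based array indices)
voxel_centers <- function(grid, idx) {
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Centroid of the cavity
#'
#' Unweighted centroid of cavity voxel centers in physical coordinates (cm):
#' the fiber tip placement point. For non-convex (e.g. horseshoe) cavities
#' the centroid can fall outside the cavity itself; it is still returned,
#' with `inside = FALSE` flagged, since the clinical fiber is advanced only
#' to the approximate center.
#'
#' @param grid a [label_grid()].
#' @return list with `point` (cm), `inside` (logical), and `voxel`
#'   (1-based index of the voxel containing the point).
#' @export
cavity_center_of_mass <- function(grid) {
  stopifnot(is_label_grid(grid))
  idx <- which(grid$labels == 2L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty geometry: no cavity voxels")
  ctr <- colMeans(voxel_centers(grid, idx))
  vox <- pmin(pmax(round((ctr - grid$origin) / grid$spacing) + 1, 1),
              dim(grid$labels))
  inside <- grid$labels[matrix(as.integer(vox), 1)] == 2L
  if (!inside)
    warning("cavity centroid falls outside the cavity (non-convex shape)")
  list(point = unname(ctr), inside = inside, voxel = as.integer(vox))
}

#' Extract the wall shell around a binary cavity mask
#'
#' Builds the three-region geometry from a binary cavity mask: wall voxels
#' are exactly the non-cavity voxels whose centers lie within Euclidean
#' distance `thickness` of a cavity voxel center (a thresholded distance
#' transform); everything else is exterior. For a voxelized sphere of
#' radius r this approximates the shell from r to r + `thickness`,
#' converging as the spacing shrinks (the digitized shell runs about a
#' third of a voxel thin at its outer edge).
#'
#' @param cavity 3D logical (or 0/1) array marking cavity voxels.
#' @param spacing voxel spacing, cm (length 3 or scalar).
#' @param thickness wall shell thickness, cm; must be at least
#'   `max(spacing)` so the shell separates cavity from exterior.
#' @param origin physical coordinate of the first voxel center, cm.
#' @return a [label_grid()].
#' @export
extract_wall_shell <- function(cavity, spacing, thickness = 0.2,
                               origin = spacing / 2) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(dim(cavity)) != 3L) stop("`cavity` must be a 3D array")
  cav <- array(as.logical(cavity), dim(cavity))
  if (anyNA(cav)) stop("`cavity` contains non-0/1 values")
  if (thickness < max(spacing))
    stop("wall `thickness` (", thickness, " cm) must be >= max(spacing) (",
         max(spacing), " cm) so the wall shell separates cavity from exterior")
  dil <- dilate_ball_cpp(as.vector(cav), dim(cav), spacing, thickness)
  lab <- array(0L, dim(cav))
  lab[array(dil, dim(cav))] <- 1L
  lab[cav] <- 2L
  if (!any(lab == 0L))
    warning("wall thickness spans the whole domain; no exterior voxels remain")
  label_grid(lab, spacing, if (length(origin) == 1L) rep(origin, 3) else origin,
             check = FALSE)
}

#' Cavity-facing wall surface
#'
#' The innermost wall layer: wall voxels 6-adjacent to at least one cavity
#' voxel, where "fluence rate at the abscess wall" is sampled. Each surface
#' voxel carries a representative area of 2/3 of the summed areas of its
#' cavity-facing faces: the voxelized (staircase) interface overestimates a
#' smooth surface by the orientation-averaged factor |n|_1 / |n|_2 = 3/2,
#' so the 2/3 correction recovers the smooth area exactly for spheres in
#' the fine-voxel limit (and is conservative for axis-aligned planar
#' patches). Relative weights, which are what the area-weighted dose
#' percentiles consume, remain proportional to the local interface extent.
#'
#' @param grid a [label_grid()].
#' @return object of class `wall_surface`: list with `voxels` (n x 3 1-based
#'   indices), `index` (linear indices into the label array), `area`
#'   (cm^2 per voxel), and `grid_dim`.
#' @export
wall_surface <- function(grid) {
  stopifnot(is_label_grid(grid))
  lab <- grid$labels
  d <- dim(lab)
  h <- grid$spacing
  face_area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])  # faces normal to x,y,z
  wall_idx <- which(lab == 1L, arr.ind = TRUE)
  if (nrow(wall_idx) == 0L) stop("grid has no wall voxels")
  n_faces <- matrix(0, nrow(wall_idx), 3)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- wall_idx
      nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      hit <- ok
      hit[ok] <- lab[nb[ok, , drop = FALSE]] == 2L
      n_faces[, ax] <- n_faces[, ax] + hit
    }
  }
  total_faces <- rowSums(n_faces)
  keep <- total_faces > 0
  if (!any(keep)) stop("no wall voxel is 6-adjacent to a cavity voxel")
  wall_idx <- wall_idx[keep, , drop = FALSE]
  n_faces <- n_faces[keep, , drop = FALSE]
  area <- (2 / 3) * as.vector(n_faces %*% face_area)
  structure(list(
    voxels = wall_idx,
    index = as.integer(wall_idx[, 1] + d[1] * ((wall_idx[, 2] - 1) +
                                                 d[2] * (wall_idx[, 3] - 1))),
    area = area,
    grid_dim = d
  ), class = "wall_surface")
}

#' @export
print.wall_surface <- function(x, ...) {
  cat("wall_surface: ", nrow(x$voxels), " voxels, total area ",
      signif(sum(x$area), 4), " cm^2\n", sep = "")
  invisible(x)
}
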