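#' Read and write segmentation masks as NIfTI-1
#'
#' Label grids are stored as NIfTI-1 integer volumes with spacing in the
#' header (mm in the file, converted to cm internally). `load_mask()` accepts
#' either a full three-region label map (values 0/1/2) or a binary cavity
#' mask (values 0/1), in which case the wall shell of the given thickness is
#' extracted around the cavity.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param wall_thickness shell thickness (cm) used when the file is a binary
#'   cavity mask.
#' @return `load_mask()` returns a [label_grid()].
#' @export
load_mask <- function(path, wall_thickness = 0.2) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (any(abs(vals - round(vals)) > 1e-6))
    stop("format error: mask contains non-integer voxel values")
  vals <- array(as.integer(round(vals)), dim(vals))
  if (length(dim(vals)) != 3L)
    stop("format error: expected a 3D volume")
  pd <- RNifti::pixdim(img)
  spacing_cm <- as.numeric(pd[1:3]) * 0.1  # header mm -> cm
  uniq <- sort(unique(as.vector(vals)))
  if (!any(uniq > 0L))
    stop("empty geometry: mask contains no cavity voxels")
  if (all(uniq %in% c(0L, 1L))) {
    extract_wall_shell(vals == 1L, spacing_cm, wall_thickness)
  } else if (all(uniq %in% 0:2)) {
    if (!any(vals == 2L))
      stop("empty geometry: label map contains no cavity voxels")
    label_grid(vals, spacing_cm)
  } else {
    stop("format error: voxel values must be in {0,1} or {0,1,2}, got ",
         paste(utils::head(uniq, 5), collapse = ", "))
  }
}

#' @rdname load_mask
#' @param grid a [label_grid()].
#' @export
save_mask <- function(grid, path) {
  stopifnot(is_label_grid(grid))
  img <- RNifti::asNifti(grid$labels, pixdim = grid$spacing * 10)  # cm -> mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a fluence map as NIfTI-1 plus a JSON sidecar
#'
#' The volume holds per-voxel fluence rate per unit delivered power
#' (cm^-2); the sidecar records photon count, seed, absorbed and escaped
#' fractions, and delivered power, so every map is traceable to its run.
#'
#' @param map a `fluence_map` from [simulate_fluence()].
#' @param path output path (`.nii`); the sidecar is written alongside as
#'   `<path>.json`.
#' @export
save_fluence <- function(map, path) {
  stopifnot(inherits(map, "fluence_map"))
  img <- RNifti::asNifti(map$values, pixdim = map$spacing * 10)
  RNifti::writeNifti(img, path)
  side <- list(n_photons = map$n_photons, seed = map$seed,
               absorbed = map$absorbed, escaped = map$escaped,
               power_mw = map$power_mw, units = "cm^-2 per mW",
               source = map$source)
  # 17 significant digits so the tallies round-trip bit-exactly
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_fluence
#' @export
load_fluence <- function(path) {
  img <- RNifti::readNifti(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("malformed fluence file: missing sidecar ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  vals <- as.array(img)
  structure(list(values = vals,
                 spacing = as.numeric(RNifti::pixdim(img)[1:3]) * 0.1,
                 origin = as.numeric(RNifti::pixdim(img)[1:3]) * 0.05,
                 n_photons = side$n_photons, seed = side$seed,
                 absorbed = side$absorbed, escaped = side$escaped,
                 power_mw = side$power_mw, source = side$source),
            class = "fluence_map")
}
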