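#' Specification of a synthetic abscess phantom
#'
#' Describes a closed single-cavity phantom of the kind used to stand in for
#' segmented patient CT volumes: spherical, ellipsoidal, or lobulated
#' (irregular, concave) cavities up to 8 cm maximum diameter, voxelized on a
#' CT-like (possibly anisotropic) grid and partitioned into exterior / wall /
#' cavity regions.
#'
#' The 8-cm diameter cap mirrors the clinical exclusion criterion for
#' intracavity PDT; specs exceeding it are refused.
#'
#' @param shape one of `"sphere"`, `"ellipsoid"`, `"lobulated"`.
#' @param radius sphere radius, cm (sphere only; shorthand for equal
#'   `semi_axes`).
#' @param semi_axes length-3 semi-axes, cm (ellipsoid / lobulated).
#' @param n_lobules number of lobules (lobulated only).
#' @param lobule_amplitude radial jitter of lobule centers, cm
#'   (lobulated only).
#' @param wall_thickness wall shell thickness, cm. The default 0.2 cm (two
#'   voxels at the default spacing) matches the scale of the enhancing rim
#'   seen on CT and exceeds one transport mean free path at
#'   `mu_s = 100 cm^-1`, `g = 0.9`.
#' @param spacing voxel spacing, cm (scalar or length 3).
#' @param padding exterior tissue margin beyond the wall, cm; at least 1 cm
#'   so that domain truncation does not perturb the fluence at the wall.
#' @param seed integer seed controlling lobule jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid", "lobulated"),
                         radius = NULL, semi_axes = NULL,
                         n_lobules = 4, lobule_amplitude = 0.5,
                         wall_thickness = 0.2, spacing = 0.1,
                         padding = 1.0, seed = 1L) {
  shape <- match.arg(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(semi_axes)) {
    if (is.null(radius)) stop("give either `radius` or `semi_axes`")
    semi_axes <- rep(radius, 3)
  }
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("`semi_axes` must be three positive lengths (cm)")
  if (any(semi_axes < max(spacing)))
    stop("degenerate geometry: cavity radius smaller than one voxel")
  if (wall_thickness < max(spacing))
    stop("invalid spec: wall thickness (", wall_thickness,
         " cm) below voxel spacing (", max(spacing), " cm)")
  amp <- if (shape == "lobulated") lobule_amplitude else 0
  if (shape == "lobulated" && (n_lobules < 1 || amp < 0))
    stop("lobulated shape needs n_lobules >= 1 and lobule_amplitude >= 0")
  max_diam <- 2 * (max(semi_axes) + amp)
  if (max_diam > 8)
    stop("maximum cavity diameter ", signif(max_diam, 3),
         " cm exceeds the 8 cm eligibility limit (abscess diameter > 8 cm ",
         "is an exclusion criterion)")
  structure(list(shape = shape, semi_axes = semi_axes,
                 n_lobules = as.integer(n_lobules), lobule_amplitude = amp,
                 wall_thickness = wall_thickness, spacing = spacing,
                 padding = padding, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a private, seeded RNG stream; global .Random.seed untouched
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Generate a voxelized abscess phantom
#'
#' Rasterizes the analytic cavity described by a [phantom_spec()] (voxel
#' centers inside the shape), surrounds it with a wall shell of the
#' configured thickness, and embeds it in exterior tissue with the
#' configured padding. Lobulated cavities are the union of the base
#' ellipsoid and `n_lobules` jittered, shrunken ellipsoids (largest
#' 6-connected component kept), which produces the concave, irregular
#' morphologies seen in pelvic abscesses. Deterministic given the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_grid()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$spacing
  reach <- max(spec$semi_axes) + spec$lobule_amplitude
  margin <- spec$wall_thickness + spec$padding
  half <- rep(reach + margin, 3)
  dims <- pmax(ceiling(2 * half / h), 3)
  ctr <- dims * h / 2            # domain center, cm (corner at 0)
  origin <- h / 2
  x <- origin[1] + (seq_len(dims[1]) - 1) * h[1]
  y <- origin[2] + (seq_len(dims[2]) - 1) * h[2]
  z <- origin[3] + (seq_len(dims[3]) - 1) * h[3]

  inside_ellipsoid <- function(c0, ax) {
    qx <- ((x - c0[1]) / ax[1])^2
    qy <- ((y - c0[2]) / ax[2])^2
    qz <- ((z - c0[3]) / ax[3])^2
    outer(outer(qx, qy, `+`), qz, `+`) <= 1
  }

  cav <- inside_ellipsoid(ctr, spec$semi_axes)
  if (spec$shape == "lobulated") {
    lob <- with_private_seed(spec$seed, {
      lapply(seq_len(spec$n_lobules), function(k) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        r <- spec$lobule_amplitude * stats::runif(1, 0.5, 1)
        ax <- spec$semi_axes * stats::runif(3, 0.45, 0.8)
        list(center = ctr + r * u, axes = ax)
      })
    })
    for (lb in lob) cav <- cav | inside_ellipsoid(lb$center, lb$axes)
    comp <- array(label_components6_cpp(as.vector(cav), dims), dims)
    if (max(comp) > 1L) {
      keep <- which.max(tabulate(comp[comp > 0L]))
      cav <- comp == keep
    }
  }
  if (!any(cav)) stop("degenerate geometry: no voxel center falls inside the cavity")
  grid <- extract_wall_shell(cav, h, spec$wall_thickness, origin)
  validate_label_grid(grid)
  grid
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec: ", x$shape, ", semi-axes ",
      paste(signif(x$semi_axes, 3), collapse = "/"), " cm",
      if (x$shape == "lobulated")
        paste0(", ", x$n_lobules, " lobules (amplitude ",
               signif(x$lobule_amplitude, 3), " cm)"),
      ", wall ", x$wall_thickness, " cm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read / write a phantom spec as YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param spec a [phantom_spec()] (for writing).
#' @return `read_phantom_spec()` returns a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(phantom_spec)))
  do.call(phantom_spec, vals[keep])
}

#' @rdname read_phantom_spec
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(unclass(spec), path)
  invisible(path)
}
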