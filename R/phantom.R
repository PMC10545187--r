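#' Default murine-like retinal layer stack
#'
#' Fixture convention for the phantom generator: layer names follow the
#' standard retinal strata (nerve fiber, ganglion cell, inner plexiform,
#' inner nuclear, outer plexiform, outer nuclear layers) and the first three
#' sum to a 120 um upper retinal cell layer (URCL), the scale observed in
#' healthy fixed murine retina. Reflectivities are free parameters of the
#' phantom, chosen so that both target interfaces (medium-retina, IPL-INL)
#' are dark-to-bright transitions detectable as strong positive axial
#' gradients.
#'
#' @return `data.frame` with columns `name`, `thickness_um`, `reflectivity`.
#' @export
default_retina_layers <- function() {
  data.frame(
    name = c("NFL", "GCL", "IPL", "INL", "OPL", "ONL"),
    thickness_um = c(15, 25, 80, 30, 20, 60),
    reflectivity = c(0.50, 0.25, 0.15, 0.45, 0.20, 0.55),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic layered-retina OCT phantom
#'
#' Describes a tissue slab of stacked retinal layers inside a low-scattering
#' embedding medium, imaged on an OPL axial grid. The defaults emulate a
#' healthy murine retina embedded in a gel (n = 1.33): URCL (NFL+GCL+IPL)
#' of 120 um geometric thickness, speckle contrast 0.3, 1 OPL um axial
#' sampling, 5 um lateral A-scan pitch over a ~1 mm wide B-scan (the scale of
#' the region evaluated around the optic nerve head), and 4 um B-scan
#' separation.
#'
#' @param layers `data.frame` with `name`, `thickness_um` (> 0, geometric)
#'   and `reflectivity` (in \[0, 1\]), ordered top to bottom.
#' @param n_medium refractive index of the embedding medium (>= 1).
#' @param medium_reflectivity mean reflectivity of the medium, in \[0, 1\].
#' @param top_depth_um geometric depth of the medium-retina interface below
#'   the volume top (um). Physically this placement derives from keeping the
#'   specimen well below the medium surface (on the order of twice the
#'   system's depth of focus); here it is a free geometry parameter.
#' @param curvature_um peak sagitta (um, geometric) of a smooth parabolic
#'   bowing of the whole layer stack across x: zero at the B-scan centre,
#'   `curvature_um` at the lateral edges (eyecup-like cup shape). The bowing
#'   is rigid: all interfaces shift identically.
#' @param speckle_contrast intensity SD / mean within homogeneous regions,
#'   in \[0, 1\]; 0 disables all noise.
#' @param spacing voxel spacing `(z, x, y)` um; `z` in OPL um.
#' @param shape volume shape `(n_z, n_x, n_y)`.
#' @param i2_after_layer name of the layer whose lower boundary is the second
#'   target interface i2 (default `"IPL"`, giving the IPL-INL interface).
#' @param seed integer RNG seed; generation is bit-reproducible given the
#'   full spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(layers = default_retina_layers(),
                         n_medium = 1.33,
                         medium_reflectivity = 0.04,
                         top_depth_um = 40,
                         curvature_um = 0,
                         speckle_contrast = 0.3,
                         spacing = c(z = 1, x = 5, y = 4),
                         shape = c(480L, 200L, 133L),
                         i2_after_layer = "IPL",
                         seed = 1L) {
  spec <- structure(
    list(layers = layers, n_medium = n_medium,
         medium_reflectivity = medium_reflectivity,
         top_depth_um = top_depth_um, curvature_um = curvature_um,
         speckle_contrast = speckle_contrast,
         spacing = stats::setNames(as.numeric(spacing), c("z", "x", "y")),
         shape = as.integer(shape), i2_after_layer = i2_after_layer,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ly <- spec$layers
  if (!is.data.frame(ly) || nrow(ly) < 1L ||
      !all(c("name", "thickness_um", "reflectivity") %in% names(ly)))
    stop("layers: need a data.frame with name, thickness_um, reflectivity",
         call. = FALSE)
  if (any(ly$thickness_um <= 0))
    stop("layers: all thicknesses must be > 0", call. = FALSE)
  if (any(ly$reflectivity < 0 | ly$reflectivity > 1))
    stop("layers: reflectivities must be in [0, 1]", call. = FALSE)
  if (spec$medium_reflectivity < 0 || spec$medium_reflectivity > 1)
    stop("medium_reflectivity: must be in [0, 1]", call. = FALSE)
  if (spec$n_medium < 1)
    stop("n_medium: refractive index must be >= 1", call. = FALSE)
  if (spec$top_depth_um < 0)
    stop("top_depth_um: must be >= 0", call. = FALSE)
  if (spec$curvature_um < 0)
    stop("curvature_um: must be >= 0", call. = FALSE)
  if (spec$speckle_contrast < 0 || spec$speckle_contrast > 1)
    stop("speckle_contrast: must be in [0, 1]", call. = FALSE)
  if (length(spec$shape) != 3L || any(spec$shape < 1L))
    stop("shape: must be 3 positive integers (n_z, n_x, n_y)", call. = FALSE)
  if (any(spec$spacing <= 0))
    stop("spacing: entries must be > 0", call. = FALSE)
  if (!spec$i2_after_layer %in% ly$name)
    stop("i2_after_layer: no layer named '", spec$i2_after_layer, "'",
         call. = FALSE)
  extent_opl <- spec$n_medium *
    (spec$top_depth_um + spec$curvature_um + sum(ly$thickness_um))
  if (extent_opl > spec$shape[1] * spec$spacing[["z"]])
    stop("shape: layer stack (", round(extent_opl, 1),
         " OPL um) does not fit inside n_z * axial spacing", call. = FALSE)
  invisible(spec)
}

# Parabolic bowing profile: 0 at the lateral centre, `sag` at the edges.
curvature_profile <- function(x_um, sag) {
  if (sag == 0) return(rep(0, length(x_um)))
  xc <- mean(range(x_um))
  half <- diff(range(x_um)) / 2
  sag * ((x_um - xc) / half)^2
}

#' Generate a synthetic OCT phantom volume with exact ground truth
#'
#' Builds the reflectivity map implied by the spec (layer boundaries snapped
#' to the nearest voxel centre, no partial-volume blending), realizes speckle
#' as multiplicative gamma-distributed intensity noise with shape
#' `1 / speckle_contrast^2` and unit mean (so the intensity mean equals the
#' reflectivity and SD/mean equals the contrast within homogeneous regions),
#' and returns the exact analytic interface curves in OPL axial units. Voxels
#' whose region reflectivity is exactly zero receive a small positive
#' exponential noise floor (mean 1% of the maximum layer reflectivity) so
#' background-noise ROI measurements stay nondegenerate; with
#' `speckle_contrast = 0` the generator is fully deterministic and noise-free.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `volume` (an [oct_volume()]) and `truth`
#'   (class `phantom_truth`: per-y exact interface depths `z_i1_opl`,
#'   `z_i2_opl` as `(n_x, n_y)` matrices in OPL um, the true geometric
#'   thickness map and the scalar design URCL thickness).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  n_z <- spec$shape[1]; n_x <- spec$shape[2]; n_y <- spec$shape[3]
  sp <- spec$spacing
  x_um <- (seq_len(n_x) - 1) * sp[["x"]]
  sag <- curvature_profile(x_um, spec$curvature_um)
  bounds_geo <- spec$top_depth_um + c(0, cumsum(spec$layers$thickness_um))
  # exact OPL depth of every interface, per lateral column: (n_x, n_bounds)
  z_bounds <- (outer(sag, bounds_geo, "+")) * spec$n_medium
  refl <- c(spec$medium_reflectivity, spec$layers$reflectivity,
            spec$medium_reflectivity)
  z_centres <- (seq_len(n_z) - 1) * sp[["z"]]
  region <- matrix(1L, n_z, n_x)
  for (k in seq_len(ncol(z_bounds)))
    region <- region + outer(z_centres, z_bounds[, k], ">=")
  plane_refl <- matrix(refl[region], n_z, n_x)
  base <- array(plane_refl, c(n_z, n_x, n_y))
  intensity <- withr::with_seed(
    spec$seed,
    add_speckle(base, spec$speckle_contrast, max(spec$layers$reflectivity)),
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion"
  )
  i2_col <- match(spec$i2_after_layer, spec$layers$name) + 1L
  volume <- oct_volume(
    intensity, sp, spec$n_medium,
    meta = list(seed = spec$seed, spec_hash = rlang::hash(unclass(spec)),
                generator = "octlayer phantom")
  )
  truth <- structure(
    list(
      x_um = x_um,
      z_i1_opl = matrix(z_bounds[, 1L], n_x, n_y),
      z_i2_opl = matrix(z_bounds[, i2_col], n_x, n_y),
      thickness_map_um = matrix(
        (z_bounds[, i2_col] - z_bounds[, 1L]) / spec$n_medium, n_x, n_y),
      urcl_design_um = sum(spec$layers$thickness_um[seq_len(i2_col - 1L)]),
      n_medium = spec$n_medium
    ),
    class = "phantom_truth"
  )
  list(volume = volume, truth = truth)
}

add_speckle <- function(base, contrast, max_refl) {
  if (contrast <= 0) return(base)
  shape <- 1 / contrast^2
  out <- base * array(stats::rgamma(length(base), shape = shape, rate = shape),
                      dim(base))
  zero <- base == 0
  if (any(zero))
    out[zero] <- stats::rexp(sum(zero), rate = 1 / (0.01 * max_refl))
  out
}

#' Exact ground-truth interface curve of a phantom
#'
#' @param truth `phantom_truth` from [generate_phantom()].
#' @param interface `"i1"` (medium-retina) or `"i2"` (IPL-INL).
#' @param y_index 0-based B-scan index.
#' @return `data.frame` with `x_um` and `z_opl_um`.
#' @export
truth_interface <- function(truth, interface = c("i1", "i2"), y_index = 0L) {
  interface <- match.arg(interface)
  zm <- if (interface == "i1") truth$z_i1_opl else truth$z_i2_opl
  if (y_index < 0 || y_index > ncol(zm) - 1L)
    stop("y_index out of range", call. = FALSE)
  data.frame(x_um = truth$x_um, z_opl_um = zm[, y_index + 1L])
}

#' Apply a fold-like axial distortion to selected B-scan planes
#'
#' Warps both the intensities and the ground-truth curves by a raised-cosine
#' axial bump (peak `amplitude_um` OPL um at the central probed column), so
#' the distorted planes emulate the preparation artefacts that the thickness
#' evaluation excludes. Intensities shift by whole voxels (rounded); truth
#' curves shift exactly. Unaffected planes are bit-identical to the input.
#'
#' @param volume an [oct_volume()].
#' @param truth matching `phantom_truth`.
#' @param y_indices 0-based indices of the affected planes.
#' @param amplitude_um fold amplitude in OPL um (positive = deeper).
#' @param width_um lateral full width of the bump (default: half the x span).
#' @return List `(volume, truth)` with the warp applied.
#' @export
apply_distortion <- function(volume, truth, y_indices, amplitude_um,
                             width_um = NULL) {
  if (length(y_indices) == 0L) {
    warning("empty y-range: distortion not applied")
    return(list(volume = volume, truth = truth))
  }
  n_y <- dim(volume$intensity)[3]
  if (any(y_indices < 0 | y_indices > n_y - 1L))
    stop("y_indices outside volume", call. = FALSE)
  x <- truth$x_um
  if (is.null(width_um)) width_um <- diff(range(x)) / 2
  x_peak <- x[ceiling(length(x) / 2)]
  w <- ifelse(abs(x - x_peak) <= width_um / 2,
              amplitude_um * 0.5 * (1 + cos(2 * pi * (x - x_peak) / width_um)),
              0)
  shift_vox <- round(w / volume$spacing[["z"]])
  for (j in y_indices + 1L) {
    if (any(shift_vox != 0)) {
      pl <- volume$intensity[, , j]
      for (cc in which(shift_vox != 0L))
        pl[, cc] <- shift_column(pl[, cc], shift_vox[cc])
      volume$intensity[, , j] <- pl
    }
    truth$z_i1_opl[, j] <- truth$z_i1_opl[, j] + w
    truth$z_i2_opl[, j] <- truth$z_i2_opl[, j] + w
  }
  list(volume = volume, truth = truth)
}

shift_column <- function(v, s) {
  n <- length(v)
  if (s > 0) c(rep(v[1], s), v[seq_len(n - s)])
  else if (s < 0) c(v[-seq_len(-s)], rep(v[n], -s))
  else v
}

#' Write phantom ground truth as CSV plus JSON summary
#'
#' CSV columns: `y_index`, `x_um`, `z_i1_oplum`, `z_i2_oplum` (one row per
#' lateral sample per plane). The JSON summary records the design URCL
#' thickness and the refractive index.
#'
#' @param truth `phantom_truth`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the CSV path.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_y <- ncol(truth$z_i1_opl)
  df <- do.call(rbind, lapply(seq_len(n_y), function(j) {
    data.frame(y_index = j - 1L, x_um = truth$x_um,
               z_i1_oplum = truth$z_i1_opl[, j],
               z_i2_oplum = truth$z_i2_opl[, j])
  }))
  csv <- file.path(dir, "ground_truth.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(urcl_design_um = truth$urcl_design_um, n_medium = truth$n_medium,
         n_bscans = n_y, n_columns = length(truth$x_um)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}
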