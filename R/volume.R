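#' Construct an OCT intensity volume
#'
#' An `oct_volume` holds a 3D nonnegative intensity grid indexed `(z, x, y)`:
#' `z` is depth increasing downward, sampled in optical path length (OPL)
#' micrometres as delivered by a spectral-domain OCT device; `x` is the
#' lateral axis within a B-scan; `y` runs across B-scans. Voxel indices are
#' 0-based throughout the public interface and the physical coordinate of a
#' voxel centre is `index * spacing`. Conversion of the axial coordinate to
#' geometric micrometres (division by the embedding-medium refractive index)
#' is deferred to the thickness computation; the stored grid stays in OPL
#' units.
#'
#' @param intensity 3D numeric array `(n_z, n_x, n_y)`, all values finite and
#'   `>= 0`.
#' @param spacing numeric length-3 voxel spacing `(z, x, y)` in micrometres;
#'   the `z` entry is in OPL micrometres per voxel.
#' @param n_medium refractive index of the embedding medium (`>= 1`), e.g.
#'   1.33 for agarose/phytagel gels or 1.49 for epoxy resins.
#' @param meta list of provenance fields (seed, spec hash, acquisition notes).
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, spacing, n_medium = 1.33, meta = list()) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity: must be a 3D array (z, x, y)", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity: values must be finite and >= 0", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing: must be 3 positive numbers (z, x, y)", call. = FALSE)
  names(spacing) <- c("z", "x", "y")
  if (!is.numeric(n_medium) || length(n_medium) != 1L || !is.finite(n_medium) ||
      n_medium < 1)
    stop("n_medium: must be a single number >= 1", call. = FALSE)
  structure(
    list(intensity = intensity, spacing = spacing, n_medium = n_medium,
         meta = meta),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<oct_volume> %d x %d x %d voxels (z, x, y)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: z %.4g OPL um, x %.4g um, y %.4g um; n_medium %.4g\n",
              x$spacing[["z"]], x$spacing[["x"]], x$spacing[["y"]], x$n_medium))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %s\n", x$meta$seed))
  invisible(x)
}

#' Extract a single B-scan plane
#'
#' @param volume an [oct_volume()].
#' @param y_index 0-based index of the B-scan across the slow axis.
#' @return Numeric matrix `(n_z, n_x)`.
#' @export
bscan_plane <- function(volume, y_index) {
  n_y <- dim(volume$intensity)[3]
  if (length(y_index) != 1L || y_index < 0 || y_index > n_y - 1L)
    stop("y_index out of range [0, ", n_y - 1L, "]", call. = FALSE)
  volume$intensity[, , y_index + 1L]
}

#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per y-plane (`volume.tif`); spacing, refractive
#' index, intensity scale and provenance go to `volume.json`. Intensities are
#' divided by their maximum before writing (the TIFF writer expects values in
#' \[0, 1\]); the scale is recorded in the sidecar and restored on read.
#'
#' @param volume an [oct_volume()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the path of the written TIFF.
#' @export
write_oct_volume <- function(volume, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(volume$intensity)
  if (scale <= 0) scale <- 1
  n_y <- dim(volume$intensity)[3]
  pages <- lapply(seq_len(n_y), function(j) volume$intensity[, , j] / scale)
  tiff::writeTIFF(pages, file.path(dir, "volume.tif"), bits.per.sample = 32L)
  sidecar <- list(
    spacing = as.list(volume$spacing),
    n_medium = volume$n_medium,
    intensity_scale = scale,
    meta = volume$meta
  )
  jsonlite::write_json(sidecar, file.path(dir, "volume.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "volume.tif"))
}

#' Read a volume written by [write_oct_volume()]
#'
#' @param dir directory containing `volume.tif` and `volume.json`.
#' @return An [oct_volume()].
#' @export
read_oct_volume <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "volume.json"),
                                 simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "volume.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (j in seq_along(pages)) arr[, , j] <- pages[[j]] * sidecar$intensity_scale
  oct_volume(arr, unlist(sidecar$spacing), sidecar$n_medium,
             as.list(sidecar$meta))
}
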