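#' Rectangular region of interest on a B-scan
#'
#' Voxel-index rectangle, 0-based, half-open at the upper bounds:
#' `z0 <= z < z1`, `x0 <= x < x1`.
#'
#' @param x0,x1,z0,z1 bounds in voxel indices.
#' @param y_index 0-based B-scan index the ROI refers to.
#' @param tag descriptive tag, e.g. `"above-sample"`.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(x0, x1, z0, z1, y_index = 0L, tag = "above-sample") {
  if (x1 <= x0 || z1 <= z0)
    stop("ROI is empty: need x0 < x1 and z0 < z1", call. = FALSE)
  if (x0 < 0 || z0 < 0)
    stop("ROI bounds must be >= 0", call. = FALSE)
  structure(list(x0 = as.integer(x0), x1 = as.integer(x1),
                 z0 = as.integer(z0), z1 = as.integer(z1),
                 y_index = as.integer(y_index), tag = tag),
            class = "roi_spec")
}

#' Background-noise metric of an embedding medium
#'
#' Population standard deviation (denominator N) of the gray levels inside a
#' sample-free ROI above the specimen, computed on the preprocessed B-scan.
#' The value is in post-stretch intensity units and is only comparable
#' between measurements made with an identical preprocessing configuration,
#' which is why the preprocessing provenance travels with the report.
#'
#' @param plane preprocessed B-scan matrix `(n_z, n_x)`.
#' @param roi an [roi_spec()].
#' @param sample_mask optional logical matrix of the same shape marking
#'   sample voxels; the ROI must not intersect it.
#' @param provenance optional list recorded verbatim (e.g. the preprocessing
#'   config hash).
#' @return Object of class `noise_report` with `sigma_bg`, `n_voxels`, the
#'   ROI and the provenance.
#' @export
background_noise <- function(plane, roi, sample_mask = NULL,
                             provenance = NULL) {
  n_z <- nrow(plane); n_x <- ncol(plane)
  if (roi$z1 > n_z || roi$x1 > n_x)
    stop("ROI outside plane bounds", call. = FALSE)
  zi <- (roi$z0 + 1L):roi$z1
  xi <- (roi$x0 + 1L):roi$x1
  if (!is.null(sample_mask)) {
    if (!identical(dim(sample_mask), dim(plane)))
      stop("sample_mask shape differs from plane", call. = FALSE)
    if (any(sample_mask[zi, xi]))
      stop("ROI contains sample", call. = FALSE)
  }
  v <- plane[zi, xi]
  sigma <- sqrt(mean((v - mean(v))^2))
  structure(list(sigma_bg = sigma, n_voxels = length(v), roi = unclass(roi),
                 provenance = provenance),
            class = "noise_report")
}

#' Curvature-energy distortion score of an interface curve
#'
#' Integrated squared second difference of the rasterized curve, normalized
#' by the lateral span: zero for straight lines, invariant under rigid
#' translation, and strictly larger for folded or warped interfaces. Used as
#' an optional automated surrogate for the operator's discard of B-scans
#' with significant retina distortion; it is reported, never applied as an
#' automatic exclusion rule by default.
#'
#' @param curve an `interface_curve`, or a numeric vector of z values on a
#'   uniform raster.
#' @param spacing_x raster pitch in um (used for both rasterization of a
#'   curve and normalization).
#' @return Nonnegative scalar score (um^-3).
#' @export
distortion_score <- function(curve, spacing_x = 1) {
  if (inherits(curve, "interface_curve")) {
    x <- seq(curve$domain[1], curve$domain[2], by = spacing_x)
    z <- eval_interface(curve, x)
  } else {
    z <- as.numeric(curve)
  }
  if (length(z) < 3L) return(0)
  span <- (length(z) - 1L) * spacing_x
  d2 <- diff(z, differences = 2L) / spacing_x^2
  sum(d2^2) * spacing_x / span
}
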