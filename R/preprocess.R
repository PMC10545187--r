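#' Volume preprocessing configuration
#'
#' Bundles the parameters of the conditioning chain applied to acquired
#' volumes before segmentation: separable 3D Gaussian filtering (defaults
#' sigma = 1.0 voxel on the z and x axes, 2.0 on y), linear histogram
#' stretching between two intensity quantiles, and optional averaging of
#' consecutive B-scans. Stages are applied in the order
#' filter -> stretch -> average.
#'
#' @param sigma_xz Gaussian SD in voxels applied to the z and x axes.
#' @param sigma_y Gaussian SD in voxels applied to the y axis.
#' @param stretch_low,stretch_high intensity quantiles mapped to 0 and 1
#'   (defaults 0.001 / 0.999; quantile clipping is robust to hot pixels).
#' @param n_average odd number of consecutive B-scans averaged per output
#'   plane; 1 disables averaging.
#' @param stretch_mode `"quantile"` (default) or `"minmax"` (plain min/max
#'   stretching, ignoring the quantile parameters).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sigma_xz = 1.0, sigma_y = 2.0,
                              stretch_low = 0.001, stretch_high = 0.999,
                              n_average = 1L,
                              stretch_mode = c("quantile", "minmax")) {
  stretch_mode <- match.arg(stretch_mode)
  if (sigma_xz < 0 || sigma_y < 0)
    stop("sigma_xz/sigma_y: must be >= 0", call. = FALSE)
  if (stretch_low < 0 || stretch_high > 1 || stretch_low >= stretch_high)
    stop("stretch_low/stretch_high: need 0 <= low < high <= 1", call. = FALSE)
  n_average <- as.integer(n_average)
  if (n_average < 1L || n_average %% 2L == 0L)
    stop("n_average: must be an odd integer >= 1", call. = FALSE)
  structure(
    list(sigma_xz = sigma_xz, sigma_y = sigma_y,
         stretch_low = stretch_low, stretch_high = stretch_high,
         n_average = n_average, stretch_mode = stretch_mode),
    class = "preprocess_config"
  )
}

# Unit-sum 1D Gaussian kernel truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- ceiling(truncate * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Fold arbitrary (possibly out-of-range) indices back into 1..n by symmetric
# reflection about the array edges (edge sample repeated: ... 2 1 | 1 2 ...).
sym_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Separable convolution of a 3D array along one axis with symmetric
# ("reflect") boundary handling.
convolve_axis <- function(a, w, axis) {
  r <- (length(w) - 1L) / 2L
  if (r == 0L) return(a * w)
  d <- dim(a)
  n <- d[axis]
  idx <- sym_index(seq_len(n + 2L * r) - r, n)
  padded <- switch(axis,
                   a[idx, , , drop = FALSE],
                   a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
  out <- array(0, d)
  for (k in seq_along(w)) {
    sl <- (k - 1L) + seq_len(n)
    out <- out + w[k] * switch(axis,
                               padded[sl, , , drop = FALSE],
                               padded[, sl, , drop = FALSE],
                               padded[, , sl, drop = FALSE])
  }
  out
}

#' 3D Gaussian filtering of an OCT volume
#'
#' Separable convolution with unit-sum 1D Gaussian kernels (truncated at
#' 4 sigma, symmetric-reflection boundary handling) along each axis:
#' `sigma_xz` on z and x, `sigma_y` on y. Sigmas are in voxels. Shape and
#' metadata are preserved; all-zero sigmas return the volume unchanged.
#'
#' @param volume an [oct_volume()].
#' @param config a [preprocess_config()].
#' @return Filtered [oct_volume()].
#' @export
gaussian_filter_3d <- function(volume, config = preprocess_config()) {
  sig <- c(config$sigma_xz, config$sigma_xz, config$sigma_y)
  if (any(!is.finite(sig))) stop("sigma: must be finite", call. = FALSE)
  if (all(sig == 0)) {
    message("all-zero sigma: returning volume unchanged")
    return(volume)
  }
  a <- volume$intensity
  for (axis in 1:3) {
    if (sig[axis] > 0) a <- convolve_axis(a, gaussian_kernel_1d(sig[axis]), axis)
  }
  a[a < 0] <- 0  # guard tiny negative round-off
  out <- volume
  out$intensity <- a
  out$meta$filtered <- list(sigma_xz = config$sigma_xz, sigma_y = config$sigma_y)
  out
}

#' Linear histogram stretching
#'
#' Affine map sending the `stretch_low` / `stretch_high` intensity quantiles
#' (type-7 sample quantiles over the whole volume) to 0 and 1, clipping
#' outside; monotone non-decreasing in input intensity. `"minmax"` mode uses
#' the volume minimum and maximum instead.
#'
#' @inheritParams gaussian_filter_3d
#' @return Stretched [oct_volume()] with intensities in \[0, 1\].
#' @export
stretch_contrast <- function(volume, config = preprocess_config()) {
  v <- volume$intensity
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate histogram: volume has a single intensity value",
         call. = FALSE)
  q <- if (config$stretch_mode == "minmax") rng else
    stats::quantile(v, c(config$stretch_low, config$stretch_high),
                    names = FALSE, type = 7)
  if (q[1] == q[2])
    stop("degenerate histogram: stretch quantiles coincide", call. = FALSE)
  out <- volume
  out$intensity <- array(pmin(1, pmax(0, (v - q[1]) / (q[2] - q[1]))), dim(v))
  out$meta$stretched <- list(low = q[1], high = q[2],
                             mode = config$stretch_mode)
  out
}

#' Average adjacent B-scans
#'
#' Each output y-plane is the arithmetic mean of the `n_average` nearest
#' input planes (windows truncated at the volume edges). The y spacing
#' metadata is unchanged: the output remains on the input plane grid.
#'
#' @param volume an [oct_volume()].
#' @param n_average odd window length; 1 is the identity.
#' @return Averaged [oct_volume()].
#' @export
average_adjacent_bscans <- function(volume, n_average) {
  n_average <- as.integer(n_average)
  n_y <- dim(volume$intensity)[3]
  if (n_average < 1L || n_average %% 2L == 0L)
    stop("n_average: must be an odd integer >= 1", call. = FALSE)
  if (n_average > n_y)
    stop("n_average (", n_average, ") exceeds the number of B-scans (", n_y,
         ")", call. = FALSE)
  if (n_average == 1L) return(volume)
  half <- (n_average - 1L) %/% 2L
  a <- volume$intensity
  out_arr <- array(0, dim(a))
  for (j in seq_len(n_y)) {
    win <- max(1L, j - half):min(n_y, j + half)
    acc <- a[, , win[1]]
    for (jj in win[-1]) acc <- acc + a[, , jj]
    out_arr[, , j] <- acc / length(win)
  }
  out <- volume
  out$intensity <- out_arr
  out$meta$averaged <- list(n_average = n_average)
  out
}

#' Convert optical path length to geometric distance
#'
#' OCT measures depth as optical path length (OPL = geometric distance times
#' refractive index); dividing by the embedding-medium refractive index
#' (1.33 for agarose/phytagel gels, 1.49 for epoxy resins) recovers the
#' geometric distance.
#'
#' @param opl_um optical path length(s) in um, `>= 0`.
#' @param n_medium refractive index, `>= 1`.
#' @return Geometric distance(s) in um: `opl_um / n_medium`.
#' @export
opl_to_geometric <- function(opl_um, n_medium) {
  if (any(n_medium < 1)) stop("n_medium: must be >= 1", call. = FALSE)
  if (any(opl_um < 0)) stop("opl_um: must be >= 0", call. = FALSE)
  opl_um / n_medium
}

#' Run the full preprocessing chain
#'
#' Applies, in order: 3D Gaussian filtering, linear histogram stretching and
#' (if `n_average > 1`) consecutive-B-scan averaging. The applied
#' configuration is recorded in the volume metadata for provenance.
#'
#' @inheritParams gaussian_filter_3d
#' @return Preprocessed [oct_volume()].
#' @export
preprocess_volume <- function(volume, config = preprocess_config()) {
  out <- volume
  if (config$sigma_xz > 0 || config$sigma_y > 0)
    out <- gaussian_filter_3d(out, config)
  out <- stretch_contrast(out, config)
  if (config$n_average > 1L)
    out <- average_adjacent_bscans(out, config$n_average)
  out$meta$preprocess <- unclass(config)
  out
}
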