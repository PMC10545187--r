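#' Build a sampling-point set
#'
#' Sampling points mark an interface (`"i1"`: medium-retina; `"i2"`:
#' IPL-INL) on one B-scan as `(x_um, z_opl_um)` pairs, either placed manually
#' (read from CSV) or auto-seeded from axial gradients. The spline fit in
#' [fit_interface()] interpolates them exactly.
#'
#' @param y_index 0-based B-scan index.
#' @param interface character vector of labels (`"i1"` / `"i2"`).
#' @param x_um,z_opl_um point coordinates; x lateral um, z in OPL um.
#' @param sample_id sample identifier.
#' @param source origin tag, e.g. `"manual"` or `"auto"`.
#' @return `data.frame` of class `sampling_points`.
#' @export
sampling_points <- function(y_index, interface, x_um, z_opl_um,
                            sample_id = "sample", source = "manual") {
  df <- data.frame(sample_id = sample_id, y_index = as.integer(y_index),
                   interface = interface, x_um = as.numeric(x_um),
                   z_opl_um = as.numeric(z_opl_um), source = source,
                   stringsAsFactors = FALSE)
  class(df) <- c("sampling_points", class(df))
  df
}

#' Read / write sampling points as CSV
#'
#' CSV columns: `sample_id`, `y_index`, `interface`, `x_um`, `z_opl_um`
#' (plus optional `source`). This is the reproducible stand-in for the
#' interactive clicking step of the original analysis.
#'
#' @param path CSV file path.
#' @return For the reader, a `sampling_points` data frame.
#' @export
read_sampling_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "y_index", "interface", "x_um", "z_opl_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sampling-point CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(df$source)) df$source <- "manual"
  class(df) <- c("sampling_points", class(df))
  df
}

#' @rdname read_sampling_points
#' @param points `sampling_points` data frame to write.
#' @export
write_sampling_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Fit an interface curve through sampling points
#'
#' Interpolating natural cubic spline through the points of one interface on
#' one B-scan, sorted by x. The curve passes through every sampling point
#' exactly, is single-valued in x, and is only defined on the knot span (no
#' extrapolation). Duplicate x positions with differing z are rejected as an
#' ambiguous interface; exact duplicate points are collapsed.
#'
#' @param points a `sampling_points` data frame (may hold both interfaces).
#' @param label interface to fit, `"i1"` or `"i2"`.
#' @return Object of class `interface_curve` with fields `label`, `y_index`,
#'   `x_knots`, `z_knots`, `domain` and the spline evaluator.
#' @export
fit_interface <- function(points, label) {
  p <- as.data.frame(points)
  p <- p[p$interface == label, , drop = FALSE]
  if (nrow(p) < 2L)
    stop("need at least 2 sampling points for interface ", label,
         call. = FALSE)
  p <- p[order(p$x_um, p$z_opl_um), , drop = FALSE]
  dup <- duplicated(p[c("x_um", "z_opl_um")])
  p <- p[!dup, , drop = FALSE]
  if (anyDuplicated(p$x_um))
    stop("ambiguous interface: duplicate x with differing z", call. = FALSE)
  if (nrow(p) < 2L)
    stop("need at least 2 distinct sampling points for interface ", label,
         call. = FALSE)
  f <- stats::splinefun(p$x_um, p$z_opl_um, method = "natural")
  structure(
    list(label = label, y_index = p$y_index[1], x_knots = p$x_um,
         z_knots = p$z_opl_um, domain = range(p$x_um), fun = f),
    class = "interface_curve"
  )
}

#' Evaluate an interface curve
#'
#' @param curve an `interface_curve`.
#' @param x lateral positions (um); must lie inside the knot span.
#' @return z in OPL um at each x.
#' @export
eval_interface <- function(curve, x) {
  eps <- 1e-9 * max(1, abs(curve$domain))
  if (any(x < curve$domain[1] - eps | x > curve$domain[2] + eps))
    stop("x outside interface domain [", curve$domain[1], ", ",
         curve$domain[2], "]: no extrapolation", call. = FALSE)
  curve$fun(x)
}

# First index k of d (axial first differences) at or after `from` where a run
# of d >= thr starts; returns the position of the maximum within that run,
# i.e. the gradient peak marking the interface.
first_gradient_peak <- function(d, thr, from = 1L) {
  n <- length(d)
  if (from > n) return(NA_integer_)
  hits <- from - 1L + which(d[from:n] >= thr)
  if (length(hits) == 0L) return(NA_integer_)
  k <- hits[1]
  e <- k
  while (e < n && d[e + 1L] >= thr) e <- e + 1L
  k - 1L + which.max(d[k:e])
}

#' Auto-seed interface sampling points on a preprocessed B-scan
#'
#' Deterministic stand-in for manual point clicking: at a configurable set of
#' lateral columns, the first strong positive axial intensity gradient marks
#' the medium-retina interface (i1) and the next strong positive gradient
#' beyond a dead zone (`gap_opl_um`, skipping the interior of the URCL where
#' all transitions are dark-ward) marks the IPL-INL interface (i2). The
#' interface depth is placed at the midpoint between the two voxel centres
#' bracketing the gradient peak. Columns where either interface is
#' undetectable are dropped; fewer than two usable columns is an error.
#'
#' @param plane B-scan matrix `(n_z, n_x)`, preprocessed (filtered and
#'   stretched, so gradients are on a comparable \[0, 1\] scale).
#' @param spacing voxel spacing `(z, x, y)` um of the parent volume.
#' @param y_index 0-based index of the plane (bookkeeping).
#' @param n_columns number of probed lateral columns, spread evenly.
#' @param min_gradient absolute per-voxel gradient floor (post-stretch
#'   intensity units); planes whose gradients never reach it are unseedable.
#' @param rel_gradient relative threshold as a fraction of the strongest
#'   positive axial gradient among the probed columns.
#' @param gap_opl_um minimum axial separation (OPL um) between i1 and the
#'   start of the i2 search window.
#' @param sample_id sample identifier for the emitted points.
#' @return `sampling_points` with both interfaces at every usable column.
#' @export
auto_seed_interfaces <- function(plane, spacing, y_index = 0L,
                                 n_columns = 24L, min_gradient = 0.05,
                                 rel_gradient = 0.25, gap_opl_um = 30,
                                 sample_id = "sample") {
  n_z <- nrow(plane); n_x <- ncol(plane)
  if (n_x < 2L || n_z < 3L) stop("unseedable plane: too small", call. = FALSE)
  cols <- unique(round(seq(1L, n_x, length.out = min(n_columns, n_x))))
  D <- apply(plane[, cols, drop = FALSE], 2, diff)
  thr <- max(min_gradient, rel_gradient * max(D, 0))
  gap_vox <- max(1L, as.integer(ceiling(gap_opl_um / spacing[["z"]])))
  out <- vector("list", length(cols))
  for (ci in seq_along(cols)) {
    d <- D[, ci]
    k1 <- first_gradient_peak(d, thr, 1L)
    if (is.na(k1)) next
    k2 <- first_gradient_peak(d, thr, k1 + gap_vox)
    if (is.na(k2)) next
    out[[ci]] <- sampling_points(
      y_index = y_index, interface = c("i1", "i2"),
      x_um = (cols[ci] - 1) * spacing[["x"]],
      z_opl_um = (c(k1, k2) - 0.5) * spacing[["z"]],
      sample_id = sample_id, source = "auto")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) < 2L)
    stop("unseedable plane: fewer than 2 detectable columns", call. = FALSE)
  res <- do.call(rbind, out)
  class(res) <- c("sampling_points", "data.frame")
  res
}

#' Select the B-scan set to evaluate
#'
#' Candidate planes are the y indices inside the region of interest, stepped
#' by `round(dy_um / y_spacing)` voxels (round-half-to-even, minimum step 1).
#' Planes on the exclusion list (operator-identified distortion or folding)
#' are moved to the excluded set with a reason code. Selection is
#' deterministic and independent of intensity content.
#'
#' @param volume an [oct_volume()].
#' @param roi_y_um numeric `(lo, hi)`: y range in um, half-open at `hi`.
#' @param dy_um separation between evaluated B-scans in um (default 50).
#' @param exclusions 0-based y indices to discard.
#' @param reason reason code recorded for the exclusions.
#' @return Object of class `bscan_selection` with `candidates`, `included`,
#'   `excluded` (data frame with reasons), `step` and `n_bscans`.
#' @export
select_bscans <- function(volume, roi_y_um = NULL, dy_um = 50,
                          exclusions = integer(), reason = "distortion") {
  sp_y <- volume$spacing[["y"]]
  n_y <- dim(volume$intensity)[3]
  if (dy_um < sp_y)
    stop("dy_um must be >= the y voxel spacing (", sp_y, " um)", call. = FALSE)
  if (is.null(roi_y_um)) roi_y_um <- c(0, n_y * sp_y)
  lo <- roi_y_um[1]; hi <- roi_y_um[2]
  first <- max(0L, as.integer(ceiling(lo / sp_y - 1e-9)))
  last <- min(n_y - 1L, as.integer(ceiling(hi / sp_y - 1e-9)) - 1L)
  if (last < first)
    stop("empty ROI: no B-scan planes inside the y range", call. = FALSE)
  step <- max(1L, as.integer(round(dy_um / sp_y)))
  candidates <- seq.int(first, last, by = step)
  excluded_idx <- intersect(candidates, as.integer(exclusions))
  included <- setdiff(candidates, excluded_idx)
  structure(
    list(roi_y_um = c(lo, hi), dy_um = dy_um, step = step,
         candidates = as.integer(candidates),
         included = as.integer(included),
         excluded = data.frame(
           y_index = as.integer(excluded_idx),
           reason = rep_len(reason, length(excluded_idx)),
           stringsAsFactors = FALSE),
         n_bscans = length(included)),
    class = "bscan_selection"
  )
}

#' @export
print.bscan_selection <- function(x, ...) {
  cat(sprintf(
    "<bscan_selection> %d included, %d excluded (step %d voxels, dy %.4g um)\n",
    x$n_bscans, nrow(x$excluded), x$step, x$dy_um))
  invisible(x)
}
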