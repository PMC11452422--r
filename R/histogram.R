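# Normalized-histogram summary characteristics of scalar maps.

#' Normalized histogram of a value collection
#'
#' Equal-width bins spanning the data range, with counts divided by
#' (total count x bin width) so the histogram integrates to one — the
#' normalization used when comparing scalar-map distributions across
#' datasets of different sizes.
#'
#' @param values numeric vector (at least 2 finite values; non-finite
#'   values are dropped).
#' @param n_bins number of bins (default 1000).
#' @return List with `bin_edges` (length `n_bins + 1`), `density`
#'   (length `n_bins`) and `bin_width`.
#' @export
normalized_histogram <- function(values, n_bins = 1000L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values")
  if (n_bins < 1L) stop("`n_bins` must be at least 1")
  rng <- range(values)
  if (diff(rng) == 0)
    stop("degenerate range: all values identical")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  width <- diff(rng) / n_bins
  idx <- pmin(floor((values - rng[1]) / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(bin_edges = edges, density = counts / (length(values) * width),
       bin_width = width)
}

#' Histogram summary characteristics of a scalar map
#'
#' The four distribution characteristics used to compare scalar maps under
#' acquisition truncation: the median; the peak height (maximum normalized
#' density); the peak value (center of the tallest bin, lowest bin on
#' ties); and the peak width, defined as the difference between the 95th
#' and 5th percentiles. Percentiles use linear interpolation between order
#' statistics, so median and peak width do not depend on the binning.
#'
#' @inheritParams normalized_histogram
#' @return A `histogram_summary` object: list with `median`, `peak_height`,
#'   `peak_value`, `peak_width`, `n_bins`, `bin_edges`.
#' @export
histogram_summary <- function(values, n_bins = 1000L) {
  values <- values[is.finite(values)]
  h <- normalized_histogram(values, n_bins)
  imax <- which.max(h$density)
  q <- unname(stats::quantile(values, c(0.05, 0.5, 0.95), type = 7))
  structure(list(median = q[2],
                 peak_height = h$density[imax],
                 peak_value = (h$bin_edges[imax] + h$bin_edges[imax + 1L]) / 2,
                 peak_width = q[3] - q[1],
                 n_bins = as.integer(n_bins),
                 bin_edges = h$bin_edges),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, digits = 5, ...) {
  cat("Normalized-histogram summary (", x$n_bins, " bins)\n", sep = "")
  cat(sprintf("  median:      %.*g\n  peak height: %.*g\n  peak value:  %.*g\n  peak width:  %.*g (p95 - p5)\n",
              digits, x$median, digits, x$peak_height,
              digits, x$peak_value, digits, x$peak_width))
  invisible(x)
}

#' Histogram summary of a masked NIfTI scalar map
#'
#' Convenience entry point for real scalar maps (e.g. skeletonized
#' parameter maps): reads a NIfTI volume, keeps voxels where the mask is
#' positive (all finite voxels when no mask is given) and summarizes them
#' with [histogram_summary()]. Requires the RNifti package.
#'
#' @param map path to a NIfTI scalar map.
#' @param mask optional path to a NIfTI mask; voxels with mask > 0 enter
#'   the histogram.
#' @inheritParams normalized_histogram
#' @return A `histogram_summary` object.
#' @export
histogram_summary_nifti <- function(map, mask = NULL, n_bins = 1000L) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("histogram_summary_nifti() requires the RNifti package")
  img <- as.vector(RNifti::readNifti(map))
  if (!is.null(mask)) {
    msk <- as.vector(RNifti::readNifti(mask))
    if (length(msk) != length(img))
      stop("map and mask dimensions disagree")
    img <- img[msk > 0]
  }
  histogram_summary(img, n_bins)
}
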