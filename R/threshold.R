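#' Grey-level histogram for thresholding
#'
#' Bins intensities into `n_bins` equal-width levels over
#' `[0, max_level]`. 8-bit images map one grey level per bin; 16-bit
#' images are binned to 256 levels for threshold statistics only (feature
#' extraction always uses raw values).
#'
#' @param values numeric vector of intensities.
#' @param max_level top of the representable range (e.g. 255 or 65535).
#' @param n_bins number of histogram bins (default 256).
#' @return Object of class `grey_histogram`: integer `counts` of length
#'   `n_bins` plus the `bin_width` and `max_level` used.
#' @export
intensity_histogram <- function(values, max_level = 255, n_bins = 256) {
  if (length(values) == 0) .stop2("no intensity values to histogram")
  bw <- (max_level + 1) / n_bins
  lev <- pmin(floor(values / bw), n_bins - 1)
  counts <- tabulate(lev + 1, nbins = n_bins)
  structure(list(counts = as.integer(counts), bin_width = bw,
                 max_level = max_level), class = "grey_histogram")
}

hist_counts <- function(histogram) {
  if (inherits(histogram, "grey_histogram")) histogram$counts
  else as.numeric(histogram)
}

#' Otsu threshold of a grey-level histogram
#'
#' Returns the bin index `t` (0-based grey level) maximising the
#' between-class variance of the two classes `{levels <= t}` and
#' `{levels > t}`; pixels strictly above the threshold are foreground.
#' Ties are broken toward the lowest level.
#'
#' @param histogram a [intensity_histogram()] or a plain vector of counts
#'   per grey level starting at level 0.
#' @return Integer threshold level in `0 .. nlevels - 2`.
#' @export
otsu_threshold <- function(histogram) {
  h <- hist_counts(histogram)
  n <- length(h)
  if (sum(h > 0) < 2)
    .stop2("degenerate histogram: Otsu needs at least 2 nonempty levels")
  lev <- seq_len(n) - 1
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[n]
  w1 <- 1 - w0
  # between-class variance for threshold t = lev[i]: classes [0,t], (t,max]
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * w1[valid])
  as.integer(which.max(sigma_b) - 1L)
}

#' Triangle (Zack) threshold of a grey-level histogram
#'
#' Draws a line from the histogram peak to the farthest nonempty level on
#' the longer-tail side and returns the level between them with the
#' maximum perpendicular distance from the histogram to that line.
#' Peak ties are broken toward the lower (background-side) level; if both
#' sides reach equally far the brighter side is treated as the tail.
#'
#' @inheritParams otsu_threshold
#' @return Integer threshold level.
#' @export
triangle_threshold <- function(histogram) {
  h <- hist_counts(histogram)
  n <- length(h)
  nonempty <- which(h > 0)
  if (length(nonempty) < 2)
    .stop2("degenerate histogram: triangle needs at least 2 nonempty levels")
  peak <- which.max(h)                 # lowest index among ties
  lo <- nonempty[1]; hi <- nonempty[length(nonempty)]
  # tail side = longer reach from the peak; tie -> bright side
  end <- if ((peak - lo) > (hi - peak)) lo else hi
  if (peak == end) return(as.integer(if (end == hi) lo - 1 else end - 1))
  xs <- seq(peak, end)
  # |cross product| of (end - peak) with (x - peak); argmax is invariant
  # to histogram rescaling so raw counts are used directly
  d <- abs((end - peak) * (h[xs] - h[peak]) -
           (h[end] - h[peak]) * (xs - peak))
  step <- if (end > peak) 1L else -1L
  best <- xs[which.max(d)]             # first max scanning peak -> tail
  as.integer(best - 1L)
}

#' Average of the Otsu and triangle thresholds
#'
#' The third semi-automatic modality: the arithmetic mean of
#' [otsu_threshold()] and [triangle_threshold()] on the same histogram.
#'
#' @inheritParams otsu_threshold
#' @return Numeric threshold level (may be half-integral).
#' @export
combined_threshold <- function(histogram) {
  (otsu_threshold(histogram) + triangle_threshold(histogram)) / 2
}

compute_threshold <- function(histogram,
                              modality = c("otsu", "triangle", "average")) {
  modality <- match.arg(modality)
  switch(modality,
         otsu = otsu_threshold(histogram),
         triangle = triangle_threshold(histogram),
         average = combined_threshold(histogram))
}

# Threshold level -> raw grey value such that `pixels > value` reproduces
# `level > threshold_level` on the binned scale.
level_to_grey <- function(level, bin_width) (level + 0.5) * bin_width
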