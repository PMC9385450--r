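mask_centroid <- function(mask, weights = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights[mask]
  if (sum(w) == 0) w <- rep(1, nrow(idx))
  c(sum((idx[, 1] - 1) * w), sum((idx[, 2] - 1) * w)) / sum(w)
}

# Longest mask chord through the centroid, sampled at 1 degree steps:
# pixels within half a pixel of the line through the centroid in direction
# theta form the chord; its length is the projection extent plus one pixel.
max_chord_length <- function(mask, weights = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  if (nrow(idx) == 1) return(1)
  ctr <- mask_centroid(mask, weights)
  rr <- idx[, 1] - 1 - ctr[1]
  cc <- idx[, 2] - 1 - ctr[2]
  best <- 0
  feret <- 0
  for (deg in 0:179) {
    th <- deg * pi / 180
    dr <- cos(th); dc <- sin(th)
    proj <- rr * dr + cc * dc
    perp <- cc * dr - rr * dc
    sel <- abs(perp) <= 0.5
    if (any(sel)) {
      ext <- max(proj[sel]) - min(proj[sel]) + 1
      if (ext > best) best <- ext
    }
    feret <- max(feret, max(proj) - min(proj) + 1)
  }
  if (best == 0) feret else best    # centroid off-mask: fall back to Feret
}

#' Boundary-following perimeter estimate
#'
#' Length of the traced object contour (Moore neighbourhood), with
#' diagonal steps counted as `sqrt(2)`, including the closing step.
#' Point-like masks (fewer than 2 contour points) return 1.
#'
#' @param mask logical matrix holding one connected object.
#' @return Perimeter in pixels.
#' @export
perimeter_estimate <- function(mask) {
  if (!any(mask)) .stop2("empty mask has no perimeter")
  oc <- EBImage::ocontour(label_components(mask))
  pts <- oc[[1]]
  n <- nrow(pts)
  if (n < 2) return(1)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  sum(sqrt(rowSums((pts - nxt)^2)))
}

#' Basic region features
#'
#' Area (pixel count), max length (longest chord through the
#' intensity-weighted centroid, 1-degree sampling), and mean, population
#' standard deviation and sum of the raw intensities under the mask.
#'
#' @param image a [comet_image()] or numeric intensity matrix.
#' @param mask logical matrix, same shape.
#' @return Named list: `area`, `max_length`, `mean_intensity`,
#'   `std_intensity`, `sum_intensity`.
#' @export
region_basic_features <- function(image, mask) {
  px <- if (inherits(image, "comet_image")) image$pixels else image
  if (!all(dim(px) == dim(mask)))
    .stop2("image and mask shapes differ")
  if (!any(mask))
    return(list(area = 0, max_length = 0, mean_intensity = 0,
                std_intensity = 0, sum_intensity = 0))
  v <- px[mask]
  list(area = sum(mask),
       max_length = max_chord_length(mask, px),
       mean_intensity = mean(v),
       std_intensity = sqrt(mean((v - mean(v))^2)),
       sum_intensity = sum(v))
}

#' Sphericity of a region
#'
#' `sqrt(4 * pi * area) / perimeter`: the perimeter of the equal-area
#' circle over the object's perimeter, 1 for a perfect circle, clamped to
#' `[0, 1]` against rasterization overshoot.
#'
#' @param area region area in pixels.
#' @param perimeter region perimeter in pixels (> 0).
#' @return Sphericity in `[0, 1]`.
#' @export
sphericity <- function(area, perimeter) {
  if (perimeter <= 0) .stop2("degenerate region: perimeter must be > 0")
  min(1, sqrt(4 * pi * area) / perimeter)
}

# --- user-defined feature registry -------------------------------------

.feature_registry <- new.env(parent = emptyenv())

#' Register a user-defined comet feature
#'
#' The function receives `(image, comet_mask, head_mask, tail_mask)` and
#' must return a single numeric value; it appears as an extra column in
#' subsequent feature extractions and exports. Non-finite returns are
#' recorded as missing with a warning.
#'
#' @param name unique feature (column) name.
#' @param fn feature function.
#' @export
register_feature <- function(name, fn) {
  if (name %in% ls(.feature_registry))
    .stop2("feature '", name, "' is already registered")
  if (name %in% measurement_columns())
    .stop2("'", name, "' collides with a built-in column")
  assign(name, fn, envir = .feature_registry)
  invisible(name)
}

#' @rdname register_feature
#' @export
registered_features <- function() sort(ls(.feature_registry))

#' @rdname register_feature
#' @export
clear_registered_features <- function() {
  rm(list = ls(.feature_registry), envir = .feature_registry)
  invisible(NULL)
}

# --- full per-comet record ----------------------------------------------

#' Extract the 21 per-comet features
#'
#' Computes, per the standard comet-assay feature table: area, max length,
#' mean/std/sum intensity for comet, head and tail; sphericity for comet
#' and head; PercentDNA for head and tail
#' (`100 * region_sum / comet_sum`); and for the tail the Extent Moment
#' (`tail_max_length * tail_sum / comet_sum`) and Olive Moment (Euclidean
#' distance between head and tail centroids times
#' `tail_sum / comet_sum`). Centroids are intensity-weighted by default.
#' An empty tail yields zeros for all tail features and
#' `head_percent_dna = 100`.
#'
#' @param image a [comet_image()] or intensity matrix.
#' @param seg a [comet_segmentation()].
#' @param weighted_centroids use intensity-weighted centroids in the Olive
#'   Moment (default `TRUE`); `FALSE` uses geometric centroids.
#' @return One-row data frame with `comet_id` and the 21 features (plus
#'   any registered extra features).
#' @export
comet_features <- function(image, seg, weighted_centroids = TRUE) {
  stopifnot(inherits(seg, "comet_segmentation"))
  px <- if (inherits(image, "comet_image")) image$pixels else image
  if (!any(seg$comet_mask)) .stop2("empty comet mask")
  comet <- region_basic_features(px, seg$comet_mask)
  head_ <- region_basic_features(px, seg$head_mask)
  tail_ <- region_basic_features(px, seg$tail_mask)
  if (comet$sum_intensity <= 0)
    .stop2("comet ", seg$comet_id,
           ": total intensity is zero, PercentDNA undefined")
  wts <- if (weighted_centroids) px else NULL
  tail_frac <- tail_$sum_intensity / comet$sum_intensity
  if (any(seg$tail_mask)) {
    hc <- mask_centroid(seg$head_mask, wts)
    tc <- mask_centroid(seg$tail_mask, wts)
    olive <- sqrt(sum((hc - tc)^2)) * tail_frac
  } else olive <- 0
  rec <- data.frame(
    comet_id = seg$comet_id,
    comet_area = comet$area,
    comet_max_length = comet$max_length,
    comet_mean_intensity = comet$mean_intensity,
    comet_std_intensity = comet$std_intensity,
    comet_sum_intensity = comet$sum_intensity,
    comet_sphericity = sphericity(comet$area,
                                  perimeter_estimate(seg$comet_mask)),
    head_area = head_$area,
    head_max_length = head_$max_length,
    head_mean_intensity = head_$mean_intensity,
    head_std_intensity = head_$std_intensity,
    head_sum_intensity = head_$sum_intensity,
    head_sphericity = if (any(seg$head_mask))
      sphericity(head_$area, perimeter_estimate(seg$head_mask)) else 0,
    head_percent_dna = 100 * head_$sum_intensity / comet$sum_intensity,
    tail_area = tail_$area,
    tail_max_length = tail_$max_length,
    tail_mean_intensity = tail_$mean_intensity,
    tail_std_intensity = tail_$std_intensity,
    tail_sum_intensity = tail_$sum_intensity,
    tail_percent_dna = 100 * tail_frac,
    tail_extent_moment = tail_$max_length * tail_frac,
    tail_olive_moment = olive
  )
  for (nm in registered_features()) {
    fn <- get(nm, envir = .feature_registry)
    val <- tryCatch(fn(px, seg$comet_mask, seg$head_mask, seg$tail_mask),
                    error = function(e) NaN)
    if (!is.finite(val)) {
      warning("registered feature '", nm, "' returned a non-finite ",
              "value; recorded as missing", call. = FALSE)
      val <- NA_real_
    }
    rec[[nm]] <- val
  }
  rec
}
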