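#' Threshold settings for semi-automatic segmentation
#'
#' @param modality `"otsu"`, `"triangle"` or `"average"` (mean of the two).
#' @param comet_scale multiplicative factor applied to the
#'   comet/background threshold (default 1).
#' @param head_scale multiplicative factor applied to the head/tail
#'   threshold (default 1).
#' @param dilation_radius disc radius in pixels by which the comet mask is
#'   dilated before the head/tail split (default 0).
#' @return Object of class `threshold_settings`.
#' @export
threshold_settings <- function(modality = c("otsu", "triangle", "average"),
                               comet_scale = 1, head_scale = 1,
                               dilation_radius = 0) {
  modality <- match.arg(modality)
  if (comet_scale <= 0 || head_scale <= 0)
    .stop2("threshold scales must be positive")
  if (dilation_radius < 0) .stop2("'dilation_radius' must be >= 0")
  structure(list(modality = modality, comet_scale = comet_scale,
                 head_scale = head_scale,
                 dilation_radius = dilation_radius),
            class = "threshold_settings")
}

#' Per-comet segmentation result
#'
#' Holds the comet, head and tail binary masks in full-image coordinates.
#' Invariants: `head_mask` is a subset of `comet_mask`,
#' `tail_mask == comet_mask & !head_mask`, and the comet mask is one
#' 4-connected component.
#'
#' @param comet_mask,head_mask logical matrices (image-sized).
#' @param roi the `comet_roi` the segmentation came from, or `NULL`.
#' @param settings the [threshold_settings()] used.
#' @param comet_id integer ID.
#' @return Object of class `comet_segmentation` with the derived
#'   `tail_mask`.
#' @export
comet_segmentation <- function(comet_mask, head_mask, roi = NULL,
                               settings = threshold_settings(),
                               comet_id = 1L) {
  if (any(head_mask & !comet_mask))
    .stop2("head mask must be contained in the comet mask")
  structure(list(
    comet_mask = comet_mask,
    head_mask = head_mask,
    tail_mask = comet_mask & !head_mask,
    roi = roi,
    settings = settings,
    comet_id = as.integer(comet_id)
  ), class = "comet_segmentation")
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(mask * 1, brush)) > 0
}

# Component of `labels` with the highest peak intensity; ties broken by
# larger area, then smaller label.
select_component <- function(labels, pixels) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (length(ids) == 0) return(NULL)
  peak <- vapply(ids, function(i) max(pixels[labels == i]), numeric(1))
  area <- vapply(ids, function(i) sum(labels == i), numeric(1))
  ids[order(-peak, -area, ids)][1]
}

# Split an established comet mask into head and tail: threshold the
# comet-pixel histogram, keep the super-threshold component containing the
# comet's intensity maximum.
split_head_tail <- function(pixels, comet_mask, settings, bin_width,
                            max_grey) {
  vals <- pixels[comet_mask]
  head_mask <- comet_mask
  lev <- pmin(floor(vals / bin_width), 255)
  if (length(unique(lev)) >= 2) {
    # head/tail split always uses the averaged Otsu/triangle statistic:
    # Otsu alone shrinks the head (cuts mid-intensity head pixels into the
    # tail), triangle alone grows it (absorbs the bright tail root); their
    # mean balances the two. The user-selected modality governs the
    # comet/background stage.
    thr_level <- compute_threshold(
      intensity_histogram(vals, max_level = max_grey), "average")
    thr <- min(max(level_to_grey(thr_level, bin_width) *
                     settings$head_scale, 0), max_grey)
    hm <- comet_mask & pixels > thr
    peak_idx <- which(comet_mask)[which.max(pixels[comet_mask])]
    if (!hm[peak_idx]) {
      hm[peak_idx] <- TRUE        # head never loses the brightest pixel
    }
    comps <- label_components(hm)
    head_mask <- comps == comps[peak_idx]
    # displacement rule: an undamaged comet's sub-threshold pixels form a
    # dim rim centred on the head, not a tail; only a candidate region
    # whose centroid is displaced from the head's counts as tail
    cand <- comet_mask & !head_mask
    if (any(cand)) {
      d <- sqrt(sum((mask_centroid(cand) - mask_centroid(head_mask))^2))
      r_eq <- sqrt(sum(head_mask) / pi)
      if (d < 0.3 * r_eq) head_mask <- comet_mask
    }
  }
  head_mask
}

#' Segment one comet inside a region of interest
#'
#' Implements the semi-automatic modality: the grey-level histogram of the
#' ROI is thresholded (Otsu, triangle, or their average, per
#' `settings$modality`) to separate the comet from the background, and the
#' histogram of the comet's own pixels is thresholded again (always with
#' the averaged Otsu/triangle statistic) to separate the head from the
#' tail. The comet is the connected foreground component with the highest
#' peak intensity in the ROI; the head is the super-threshold component
#' containing the comet's intensity maximum, unless its complement is
#' centred on the head (a dim rim, not a tail), in which case the whole
#' comet is head. `comet_scale`/`head_scale` multiply the two thresholds
#' and `dilation_radius` dilates the comet mask (disc structuring element)
#' before the head/tail split.
#'
#' @param image a [comet_image()] in the bright-comet convention.
#' @param roi a `comet_roi` at least partially inside the image.
#' @param settings [threshold_settings()].
#' @param comet_id integer ID recorded on the result.
#' @return A [comet_segmentation()].
#' @export
segment_roi <- function(image, roi, settings = threshold_settings(),
                        comet_id = 1L) {
  stopifnot(inherits(image, "comet_image"))
  px <- image$pixels
  roi_mask <- rasterize_roi(roi, c(image$height, image$width))
  maxg <- max_grey(image)
  bw <- (maxg + 1) / 256
  hist <- intensity_histogram(px[roi_mask], max_level = maxg)
  thr_level <- compute_threshold(hist, settings$modality)
  thr <- min(max(level_to_grey(thr_level, bw) * settings$comet_scale, 0),
             maxg)
  fg <- roi_mask & px > thr
  if (!any(fg))
    .stop2("empty segmentation: no pixels above the comet threshold ",
           "in this ROI")
  comps <- label_components(fg)
  keep <- select_component(comps, px)
  comet_mask <- comps == keep
  comet_mask <- dilate_mask(comet_mask, settings$dilation_radius)
  head_mask <- split_head_tail(px, comet_mask, settings, bw, maxg)
  comet_segmentation(comet_mask, head_mask, roi = roi, settings = settings,
                     comet_id = comet_id)
}

#' Segment a comet from a hand-drawn contour
#'
#' The manual modality: the comet mask is the filled interior of a simple
#' polygon drawn by the user (boundary-inclusive, even-odd rule); the
#' head/tail split then follows the same intensity logic as
#' [segment_roi()]. The polygon must contain at least one pixel brighter
#' than the image-wide comet threshold, otherwise it is considered to lie
#' over background.
#'
#' @param vertices n x 2 matrix of polygon vertices, 0-based `(row, col)`.
#' @param image a [comet_image()].
#' @param settings [threshold_settings()] (used for the head split).
#' @param comet_id integer ID.
#' @return A [comet_segmentation()].
#' @export
rasterize_contour <- function(vertices, image,
                              settings = threshold_settings(),
                              comet_id = 1L) {
  stopifnot(inherits(image, "comet_image"))
  roi <- roi_polygon(vertices)
  comet_mask <- rasterize_roi(roi, c(image$height, image$width))
  px <- image$pixels
  maxg <- max_grey(image)
  bw <- (maxg + 1) / 256
  global_thr <- tryCatch(
    level_to_grey(compute_threshold(
      intensity_histogram(px, max_level = maxg), settings$modality), bw),
    error = function(e) Inf)
  if (!any(px[comet_mask] > global_thr))
    .stop2("empty segmentation: contour contains no foreground pixels")
  head_mask <- split_head_tail(px, comet_mask, settings, bw, maxg)
  comet_segmentation(comet_mask, head_mask, roi = roi, settings = settings,
                     comet_id = comet_id)
}

#' Automatically propose comet ROIs
#'
#' A classical shape-based detector standing behind a pluggable interface:
#' the image is thresholded globally (average-of-Otsu-and-triangle
#' modality), connected components are filtered by area and border
#' contact, and each surviving component yields one circular ROI padded by
#' `margin`. A learned detector can substitute by returning the same list
#' of `comet_roi` objects.
#'
#' @param image a [comet_image()].
#' @param min_area,max_area component area bounds in pixels.
#' @param margin padding added to each ROI radius, pixels.
#' @param exclude_border drop components touching the image border
#'   (default `TRUE`).
#' @param modality threshold modality for the global pass.
#' @return List of `comet_roi` circles (possibly empty).
#' @export
detect_comets <- function(image, min_area = 50, max_area = Inf,
                          margin = 5, exclude_border = TRUE,
                          modality = "average") {
  stopifnot(inherits(image, "comet_image"))
  px <- image$pixels
  maxg <- max_grey(image)
  bw <- (maxg + 1) / 256
  thr_level <- tryCatch(
    compute_threshold(intensity_histogram(px, max_level = maxg), modality),
    error = function(e) return(NULL))
  if (is.null(thr_level)) return(list())
  fg <- px > level_to_grey(thr_level, bw)
  if (!any(fg)) return(list())
  comps <- label_components(fg)
  n_comp <- max(comps)
  h <- nrow(px); w <- ncol(px)
  areas <- tabulate(comps[comps > 0L], nbins = n_comp)
  keep <- which(areas >= min_area & areas <= max_area)
  if (exclude_border) {
    border <- unique(c(comps[1, ], comps[h, ], comps[, 1], comps[, w]))
    keep <- setdiff(keep, border)
  }
  rois <- list()
  for (i in keep) {
    idx <- which(comps == i, arr.ind = TRUE)
    ctr <- colMeans(idx) - 1           # 0-based (row, col)
    rad <- sqrt(max((idx[, 1] - 1 - ctr[1])^2 +
                    (idx[, 2] - 1 - ctr[2])^2))
    rois[[length(rois) + 1]] <- roi_circle(ctr, rad + margin)
  }
  rois
}
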