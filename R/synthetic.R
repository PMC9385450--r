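#' Map tail DNA fraction to the conventional 5 damage classes
#'
#' Class 1 holds undamaged comets (no or barely detectable tail) and
#' class 5 comets that are mostly tail; bin edges on the fraction of total
#' comet intensity in the tail are 0.05, 0.25, 0.5 and 0.8.
#'
#' @param tail_fraction numeric vector in `[0, 1]`.
#' @return Integer class labels 1-5.
#' @export
class_from_tail_fraction <- function(tail_fraction) {
  stopifnot(all(tail_fraction >= 0 & tail_fraction <= 1))
  findInterval(tail_fraction, c(0.05, 0.25, 0.5, 0.8)) + 1L
}

#' Parameters of one synthetic comet
#'
#' @param center `(row, col)` position of the head center, 0-based, within
#'   the patch or image the comet is rendered into.
#' @param head_radius head disc radius, pixels.
#' @param head_peak peak head intensity, grey levels.
#' @param tail_length tail extent beyond the head boundary, pixels.
#' @param tail_fraction fraction of the comet's integrated intensity in
#'   the tail, in `[0, 0.99]`; 0 if and only if `tail_length` is 0.
#' @param orientation tail direction, radians (from +col axis toward
#'   +row).
#' @param class_label integer damage class (defaults to the tail-fraction
#'   bin of [class_from_tail_fraction()]).
#' @return Object of class `comet_params`.
#' @export
comet_params <- function(center, head_radius, head_peak, tail_length = 0,
                         tail_fraction = 0, orientation = 0,
                         class_label = NULL) {
  if (tail_fraction < 0 || tail_fraction > 0.99)
    .stop2("'tail_fraction' must lie in [0, 0.99]")
  if ((tail_length == 0) != (tail_fraction == 0))
    .stop2("tail_length == 0 if and only if tail_fraction == 0")
  structure(list(
    center = as.numeric(center),
    head_radius = head_radius,
    head_peak = head_peak,
    tail_length = tail_length,
    tail_fraction = tail_fraction,
    orientation = orientation,
    class_label = class_label %||% class_from_tail_fraction(tail_fraction)
  ), class = "comet_params")
}

default_patch_shape <- function(params) {
  side <- 2 * ceiling(params$head_radius + params$tail_length) + 9
  c(side, side)
}

#' Render one noiseless synthetic comet
#'
#' The head is an isotropic Gaussian-profile disc (sigma = radius / 2);
#' the tail is a one-sided lobe along `orientation` with exponential axial
#' decay and Gaussian cross-section, scaled so that the integrated tail
#' intensity over the total equals `tail_fraction` (exact on the rendered
#' patch when nothing is truncated; a truncation warning reports the
#' achieved fraction otherwise). Rendering is deterministic; noise and
#' background belong to [generate_dataset()].
#'
#' @param params a [comet_params()]; `center` is interpreted in patch
#'   coordinates (defaults to the patch middle when `patch_shape` is
#'   `NULL`).
#' @param patch_shape `(height, width)` of the patch; `NULL` chooses a
#'   square that holds head and tail at any orientation.
#' @return List with `patch` (numeric matrix), logical `comet_mask`,
#'   `head_mask`, `tail_mask`, and `achieved_tail_fraction`.
#' @export
render_comet <- function(params, patch_shape = NULL) {
  stopifnot(inherits(params, "comet_params"))
  centered <- is.null(patch_shape)
  if (centered) patch_shape <- default_patch_shape(params)
  h <- patch_shape[1]; w <- patch_shape[2]
  ctr <- if (centered) c((h - 1) / 2, (w - 1) / 2) else params$center
  hr <- params$head_radius
  if (ctr[1] - hr < 0 || ctr[1] + hr > h - 1 ||
      ctr[2] - hr < 0 || ctr[2] + hr > w - 1)
    .stop2("comet head does not fit inside the patch")
  rows <- matrix(seq_len(h) - 1, h, w)
  cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  dr <- rows - ctr[1]; dc <- cols - ctr[2]
  d2 <- dr^2 + dc^2
  head_mask <- d2 <= hr^2
  sigma_h <- hr / 2
  H <- ifelse(head_mask, params$head_peak * exp(-d2 / (2 * sigma_h^2)), 0)

  tf <- params$tail_fraction
  if (tf > 0) {
    ur <- sin(params$orientation); uc <- cos(params$orientation)
    s <- dr * ur + dc * uc - hr        # axial distance beyond head rim
    p <- dc * ur - dr * uc             # perpendicular offset
    tail_mask <- s > 0 & s <= params$tail_length & abs(p) <= hr &
      !head_mask
    if (!any(tail_mask)) .stop2("tail mask is empty for these parameters")
    lambda <- params$tail_length / 3
    sigma_p <- hr / 2
    T_ <- ifelse(tail_mask, exp(-s / lambda) * exp(-p^2 / (2 * sigma_p^2)),
                 0)
    A <- tf / (1 - tf) * sum(H) / sum(T_)
    patch <- H + A * T_
    if (max(patch) > params$head_peak)
      patch <- patch * (params$head_peak / max(patch))
    # masks keep only pixels carrying detectable signal (>= 2 grey levels
    # after rounding): one quantization step above background is not a
    # recoverable object pixel at 8 bits
    keep <- patch >= 1.5
    head_mask <- head_mask & keep
    tail_mask <- tail_mask & keep
    patch[!keep] <- 0
    achieved <- sum(patch[tail_mask]) / sum(patch)
    # tail pixels nominally extend to ctr + hr + tail_length; warn if the
    # patch cut the lobe off and shifted the intensity split
    tip <- ctr + (hr + params$tail_length) * c(ur, uc)
    truncated <- tip[1] < 0 || tip[1] > h - 1 || tip[2] < 0 ||
      tip[2] > w - 1
    if (truncated && abs(achieved - tf) > 0.01)
      warning(sprintf(
        "tail truncated by the patch: achieved tail_fraction %.3f vs %.3f",
        achieved, tf), call. = FALSE)
  } else {
    tail_mask <- matrix(FALSE, h, w)
    patch <- H
    keep <- patch >= 1.5
    head_mask <- head_mask & keep
    patch[!keep] <- 0
    achieved <- 0
  }
  list(patch = patch, comet_mask = head_mask | tail_mask,
       head_mask = head_mask, tail_mask = tail_mask,
       achieved_tail_fraction = achieved)
}

# Sample per-comet parameters for one image. Class-1 comets have no tail;
# other classes draw the tail fraction uniformly inside their bin (class 5
# capped at 0.95 so the head keeps nonzero mass).
sample_comet_params <- function(n, class_mix, orientation,
                                orientation_jitter = 0, max_grey = 255) {
  classes <- sample.int(length(class_mix), n, replace = TRUE,
                        prob = class_mix)
  lo <- c(0, 0.05, 0.25, 0.5, 0.8)
  hi <- c(0, 0.25, 0.5, 0.8, 0.95)
  tf <- ifelse(classes == 1L, 0, runif(n, lo[classes], hi[classes]))
  data.frame(
    class_label = classes,
    tail_fraction = tf,
    tail_length = ifelse(tf == 0, 0, round(30 + 90 * tf)),
    head_radius = runif(n, 8, 14),
    head_peak = runif(n, 0.6, 0.9) * max_grey,
    orientation = orientation + rnorm(n, 0, orientation_jitter)
  )
}

place_comets <- function(shape, patches, max_tries = 200) {
  occupied <- matrix(FALSE, shape[1], shape[2])
  pos <- matrix(NA_real_, length(patches), 2)
  for (i in seq_along(patches)) {
    pm <- patches[[i]]$comet_mask
    ph <- nrow(pm); pw <- ncol(pm)
    if (ph > shape[1] || pw > shape[2])
      .stop2("could not place comet ", i, ": its ", ph, "x", pw,
             " patch exceeds the ", shape[1], "x", shape[2], " image")
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r0 <- sample.int(shape[1] - ph + 1, 1)
      c0 <- sample.int(shape[2] - pw + 1, 1)
      win <- occupied[r0:(r0 + ph - 1), c0:(c0 + pw - 1)]
      if (!any(win & pm)) {
        occupied[r0:(r0 + ph - 1), c0:(c0 + pw - 1)] <-
          win | dilate_mask(pm, 2)
        pos[i, ] <- c(r0, c0)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .stop2("could not place comet ", i, " after ", max_tries,
             " tries: density too high for this image size")
  }
  pos
}

#' Generate synthetic comet-assay images with exact ground truth
#'
#' Builds reproducible scenes of non-overlapping comets on a constant
#' background with additive Gaussian noise, plus intensity-coded label
#' masks (comet / head / tail, matching IDs) and the per-comet parameters
#' and class labels. All comets in an image share one tail orientation
#' (electrophoresis pulls every tail the same way) unless
#' `orientation_jitter > 0`. Silver-mode images are returned in acquired
#' contrast (dark comets on a bright background); [ingest_image()]
#' restores the bright-comet convention.
#'
#' @param n_images number of images.
#' @param comets_per_image `(min, max)` comets per image (count drawn
#'   uniformly).
#' @param class_mix damage-class proportions (default equal fifths).
#' @param stain_mode `"fluorescent"` (default image 1200 x 1600) or
#'   `"silver"` (default 1280 x 1024).
#' @param noise list with `gaussian_sd` (grey levels, default 5) and
#'   `background_level` (default 10).
#' @param image_shape optional `(height, width)` override.
#' @param bit_depth image bit depth (default 8).
#' @param orientation_jitter per-comet orientation SD, radians.
#' @param seed RNG seed; the same seed reproduces the dataset bit for bit.
#' @return List of length `n_images`; each element has `image`
#'   ([comet_image()]), integer `comet_mask`, `head_mask`, `tail_mask`
#'   label matrices, a `params` data frame (one row per comet, including
#'   the achieved tail fraction), and `seed`.
#' @export
generate_dataset <- function(n_images, comets_per_image = c(20, 100),
                             class_mix = rep(0.2, 5),
                             stain_mode = c("fluorescent", "silver"),
                             noise = list(gaussian_sd = 5,
                                          background_level = 10),
                             image_shape = NULL, bit_depth = 8,
                             orientation_jitter = 0, seed = 1) {
  stain_mode <- match.arg(stain_mode)
  shape <- image_shape %||%
    if (stain_mode == "fluorescent") c(1200, 1600) else c(1280, 1024)
  maxg <- 2^bit_depth - 1
  sdn <- noise$gaussian_sd %||% 5
  bg <- noise$background_level %||% 10
  with_seed(seed, lapply(seq_len(n_images), function(img_i) {
    n <- if (comets_per_image[1] == comets_per_image[2]) comets_per_image[1]
         else sample(seq(comets_per_image[1], comets_per_image[2]), 1)
    orient <- runif(1, 0, 2 * pi)
    par <- sample_comet_params(n, class_mix, orient, orientation_jitter,
                               maxg)
    patches <- lapply(seq_len(n), function(i)
      render_comet(comet_params(
        center = NULL, head_radius = par$head_radius[i],
        head_peak = par$head_peak[i], tail_length = par$tail_length[i],
        tail_fraction = par$tail_fraction[i],
        orientation = par$orientation[i],
        class_label = par$class_label[i])))
    pos <- place_comets(shape, patches)
    img <- matrix(0, shape[1], shape[2])
    comet_lab <- matrix(0L, shape[1], shape[2])
    head_lab <- matrix(0L, shape[1], shape[2])
    tail_lab <- matrix(0L, shape[1], shape[2])
    centers <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      p <- patches[[i]]
      ph <- nrow(p$patch); pw <- ncol(p$patch)
      rs <- pos[i, 1]:(pos[i, 1] + ph - 1)
      cs <- pos[i, 2]:(pos[i, 2] + pw - 1)
      img[rs, cs] <- img[rs, cs] + p$patch
      sub <- function(lab, m) { x <- lab[rs, cs]; x[m] <- i; x }
      comet_lab[rs, cs] <- sub(comet_lab, p$comet_mask)
      head_lab[rs, cs] <- sub(head_lab, p$head_mask)
      tail_lab[rs, cs] <- sub(tail_lab, p$tail_mask)
      centers[i, ] <- pos[i, ] - 1 + c((ph - 1) / 2, (pw - 1) / 2)
    }
    par$center_row <- centers[, 1]
    par$center_col <- centers[, 2]
    par$achieved_tail_fraction <-
      vapply(patches, `[[`, numeric(1), "achieved_tail_fraction")
    par$comet_id <- seq_len(n)
    px <- img + bg
    if (sdn > 0) px <- px + rnorm(length(px), 0, sdn)
    px <- round(pmin(pmax(px, 0), maxg))
    if (stain_mode == "silver") px <- maxg - px
    list(image = comet_image(px, stain_mode = stain_mode,
                             bit_depth = bit_depth),
         comet_mask = comet_lab, head_mask = head_lab,
         tail_mask = tail_lab, params = par, seed = seed)
  }))
}

#' Ground-truth feature table for synthetic comets
#'
#' Renders `n` comets (patches only, noiseless plus background) and
#' extracts the 21 features using the generator's own masks — the
#' parameter-recovery substrate for classifier validation.
#'
#' @param n number of comets.
#' @param class_mix damage-class proportions.
#' @param noise as in [generate_dataset()].
#' @param seed RNG seed.
#' @return Data frame: `class` plus the 21 feature columns.
#' @export
synthetic_feature_table <- function(n, class_mix = rep(0.2, 5),
                                    noise = list(gaussian_sd = 5,
                                                 background_level = 10),
                                    seed = 1) {
  with_seed(seed, {
    par <- sample_comet_params(n, class_mix, orientation = runif(1, 0, 2 * pi),
                               orientation_jitter = 0.5)
    rows <- lapply(seq_len(n), function(i) {
      p <- render_comet(comet_params(
        center = NULL, head_radius = par$head_radius[i],
        head_peak = par$head_peak[i], tail_length = par$tail_length[i],
        tail_fraction = par$tail_fraction[i],
        orientation = par$orientation[i]))
      px <- p$patch + (noise$background_level %||% 10)
      if ((noise$gaussian_sd %||% 5) > 0)
        px <- px + rnorm(length(px), 0, noise$gaussian_sd)
      px <- round(pmin(pmax(px, 0), 255))
      seg <- comet_segmentation(p$comet_mask, p$head_mask, comet_id = i)
      rec <- comet_features(px, seg)
      rec$class <- par$class_label[i]
      rec
    })
    do.call(rbind, rows)
  })
}

#' Circular ROIs around ground-truth comets
#'
#' Emulates the user of the semi-automatic modality drawing one circle
#' around each comet: each ROI is centered on the comet's mask centroid
#' with a radius just covering the mask plus `pad` pixels.
#'
#' @param truth one element of a [generate_dataset()] result.
#' @param pad padding added to each radius, pixels.
#' @return List of `comet_roi` circles, one per ground-truth comet ID.
#' @export
truth_rois <- function(truth, pad = 3) {
  ids <- sort(setdiff(unique(as.vector(truth$comet_mask)), 0L))
  lapply(ids, function(id) {
    idx <- which(truth$comet_mask == id, arr.ind = TRUE)
    ctr <- colMeans(idx) - 1
    rad <- sqrt(max((idx[, 1] - 1 - ctr[1])^2 + (idx[, 2] - 1 - ctr[2])^2))
    roi_circle(ctr, rad + pad)
  })
}

#' Write a synthetic dataset to disk
#'
#' Images as TIFF (as-acquired contrast), the comet/head/tail label masks
#' as 16-bit PNG, and the per-comet parameters as CSV.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset)) {
    d <- dataset[[i]]
    stem <- sprintf("image_%03d", i)
    write_comet_image(d$image, file.path(dir, paste0(stem, ".tif")))
    write_label_mask(d$comet_mask,
                     file.path(dir, paste0(stem, "_comet_mask.png")))
    write_label_mask(d$head_mask,
                     file.path(dir, paste0(stem, "_head_mask.png")))
    write_label_mask(d$tail_mask,
                     file.path(dir, paste0(stem, "_tail_mask.png")))
    par <- d$params
    par$image <- paste0(stem, ".tif")
    write.csv(par, file.path(dir, paste0(stem, "_params.csv")),
              row.names = FALSE)
  }
  invisible(dir)
}
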