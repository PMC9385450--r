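#' Comet image container
#'
#' A `comet_image` holds a 2-D matrix of non-negative grey-level
#' intensities together with its staining modality and bit depth. After
#' ingestion through [read_comet_image()] (or [ingest_image()]) comets are
#' always brighter than the background: silver-stained images, where comets
#' appear dark on a bright background, are intensity-inverted on load so a
#' single analysis path serves both stains.
#'
#' @param pixels numeric matrix of grey levels, finite and >= 0.
#' @param stain_mode `"fluorescent"` (bright comets, dark background as
#'   acquired) or `"silver"` (dark comets, bright background as acquired).
#' @param bit_depth integer, 8 or 16; intensities lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param source_path optional path the pixels were read from.
#' @param ingested `TRUE` when the pixels are already in the bright-comet
#'   analysis convention; `FALSE` for as-acquired values.
#' @return An object of class `comet_image` with fields `pixels`,
#'   `height`, `width`, `stain_mode`, `bit_depth`, `source_path`,
#'   `ingested`.
#' @export
comet_image <- function(pixels, stain_mode = c("fluorescent", "silver"),
                        bit_depth = 8, source_path = NULL,
                        ingested = FALSE) {
  stain_mode <- match.arg(stain_mode)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .stop2("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    .stop2("pixel intensities must be finite and non-negative")
  if (!bit_depth %in% c(8L, 16L))
    .stop2("'bit_depth' must be 8 or 16")
  structure(list(
    pixels = pixels,
    height = nrow(pixels),
    width = ncol(pixels),
    stain_mode = stain_mode,
    bit_depth = as.integer(bit_depth),
    source_path = source_path,
    ingested = isTRUE(ingested) || stain_mode == "fluorescent"
  ), class = "comet_image")
}

#' @export
print.comet_image <- function(x, ...) {
  cat(sprintf("comet_image: %d x %d px, %s, %d-bit, range [%g, %g]\n",
              x$height, x$width, x$stain_mode, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

max_grey <- function(image) 2^image$bit_depth - 1

rec601_luminance <- function(arr) {
  # arr: h x w x >=3 array in [0,1]
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

# Collapse whatever a reader returned (matrix, h x w x c array) to a
# grayscale matrix still on the reader's [0,1] scale.
collapse_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc == 1) return(arr[, , 1])
    if (nc == 2) return(arr[, , 1])          # gray + alpha
    return(rec601_luminance(arr))            # RGB(A)
  }
  .stop2("unsupported image array layout")
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26)
  if (length(hdr) < 26 ||
      !identical(as.integer(hdr[1:8]),
                 c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    .stop2("not a PNG file: ", path)
  as.integer(hdr[25])
}

# Minimal reader for uncompressed 8-bit palette / 24- or 32-bit BMP.
read_bmp <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  if (!identical(magic, "BM")) .stop2("not a BMP file: ", path)
  invisible(readBin(con, "integer", 2, size = 4))        # file size, reserved
  data_offset <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size < 40) .stop2("unsupported BMP header in ", path)
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 1, size = 2))        # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  compression <- readBin(con, "integer", 1, size = 4)
  if (compression != 0) .stop2("compressed BMP not supported: ", path)
  if (!bpp %in% c(8L, 24L, 32L)) .stop2("unsupported BMP bit depth: ", bpp)
  flip <- h > 0
  h <- abs(h)
  palette <- NULL
  if (bpp == 8L) {
    invisible(readBin(con, "integer", 5, size = 4))      # rest of DIB header
    n_colors <- 256L
    pal <- readBin(con, "raw", n = n_colors * 4L)
    pal <- matrix(as.integer(pal), nrow = 4)             # B, G, R, 0
    palette <- (0.299 * pal[3, ] + 0.587 * pal[2, ] + 0.114 * pal[1, ]) / 255
  }
  seek(con, data_offset)
  bytes_pp <- bpp %/% 8L
  row_bytes <- ((w * bytes_pp + 3L) %/% 4L) * 4L
  raster <- readBin(con, "raw", n = row_bytes * h)
  raster <- matrix(as.integer(raster), nrow = row_bytes)
  out <- matrix(0, nrow = h, ncol = w)
  for (r in seq_len(h)) {
    row <- raster[, r]
    if (bpp == 8L) {
      out[r, ] <- palette[row[seq_len(w)] + 1L]
    } else {
      idx <- (seq_len(w) - 1L) * bytes_pp
      b <- row[idx + 1L]; g <- row[idx + 2L]; rr <- row[idx + 3L]
      out[r, ] <- (0.299 * rr + 0.587 * g + 0.114 * b) / 255
    }
  }
  if (flip) out <- out[h:1, , drop = FALSE]
  out
}

#' Read a micrograph as a comet image
#'
#' Reads TIFF, PNG, BMP or JPEG; RGB images are collapsed to Rec. 601
#' luminance. Silver-stained images (dark comets on a bright background)
#' are intensity-inverted on load (`v -> max_grey - v`) so that in every
#' `comet_image` comets are brighter than the background.
#'
#' @param path image file path.
#' @param stain_mode `"fluorescent"` or `"silver"`.
#' @return A [comet_image()].
#' @export
read_comet_image <- function(path, stain_mode = c("fluorescent", "silver")) {
  stain_mode <- match.arg(stain_mode)
  if (!file.exists(path)) .stop2("image file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  bit_depth <- 8L
  arr <- switch(ext,
    tif = , tiff = {
      a <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) .stop2("cannot read TIFF '", path,
                                               "': ", conditionMessage(e)))
      bps <- attr(a, "bits.per.sample") %||% if (max(a) > 255) 16 else 8
      bit_depth <- if (max(bps) >= 16) 16L else 8L
      collapse_gray(a / (2^bit_depth - 1))
    },
    png = {
      bit_depth <- if (png_bit_depth(path) >= 16) 16L else 8L
      collapse_gray(tryCatch(png::readPNG(path),
                             error = function(e) .stop2("cannot read PNG '",
                               path, "': ", conditionMessage(e))))
    },
    bmp = read_bmp(path),
    jpg = , jpeg = collapse_gray(tryCatch(jpeg::readJPEG(path),
      error = function(e) .stop2("cannot read JPEG '", path, "': ",
                                 conditionMessage(e)))),
    .stop2("unsupported image format '.", ext, "' for ", path)
  )
  maxg <- 2^bit_depth - 1
  px <- round(arr * maxg)
  img <- comet_image(px, stain_mode = stain_mode, bit_depth = bit_depth,
                     source_path = path)
  ingest_image(img)
}

#' Apply the stain convention to an as-acquired image
#'
#' Silver-stained comets are dark on a bright background; this inverts
#' their intensities (`v -> max_grey - v`) so downstream segmentation and
#' features can assume bright comets regardless of stain. Fluorescent
#' images pass through unchanged, as do images already ingested
#' (idempotent). A constant (all one grey level) image triggers a
#' degenerate-input warning.
#'
#' @param image a [comet_image()] holding as-acquired pixel values.
#' @return A `comet_image` in the bright-comet convention.
#' @export
ingest_image <- function(image) {
  stopifnot(inherits(image, "comet_image"))
  if (min(image$pixels) == max(image$pixels))
    warning("degenerate image: all pixels share one grey level",
            call. = FALSE)
  if (image$stain_mode == "silver" && !image$ingested) {
    image$pixels <- max_grey(image) - image$pixels
    image$ingested <- TRUE
  }
  image
}

#' Write a comet image to disk
#'
#' Writes the as-analysis pixels back to TIFF or PNG. For silver images the
#' inversion applied at ingestion is undone first, so the file shows dark
#' comets on a bright background as acquired.
#'
#' @param image a [comet_image()].
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @export
write_comet_image <- function(image, path) {
  stopifnot(inherits(image, "comet_image"))
  px <- image$pixels
  if (image$stain_mode == "silver" && image$ingested)
    px <- max_grey(image) - px
  maxg <- max_grey(image)
  scaled <- pmin(pmax(px, 0), maxg) / maxg
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = image$bit_depth)
  } else if (ext == "png") {
    if (image$bit_depth == 8L) png::writePNG(scaled, path)
    else write_label_mask(matrix(as.integer(round(px)), nrow(px)), path)
  } else .stop2("unsupported output format '.", ext, "'")
  invisible(path)
}
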