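#' Write an intensity-coded label mask as 16-bit grayscale PNG
#'
#' A label mask is an integer matrix in which 0 is background and each
#' positive value is one object ID. Masks are stored as 16-bit grayscale
#' PNG so up to 65535 objects round-trip bit-exactly.
#'
#' @param labels integer matrix of object IDs (0 = background).
#' @param path output `.png` path.
#' @export
write_label_mask <- function(labels, path) {
  if (!is.matrix(labels)) .stop2("'labels' must be a matrix")
  lab <- as.integer(round(labels))
  if (anyNA(lab) || any(lab < 0))
    .stop2("label IDs must be non-negative integers")
  if (any(lab > 65535L))
    .stop2("label mask capacity exceeded: IDs above 65535 cannot be stored")
  dim(lab) <- dim(labels)
  .Call(cometrics_write_png16, lab, dim(lab), path.expand(path))
  invisible(path)
}

#' Read an intensity-coded label mask from PNG
#'
#' @param path PNG file path (8- or 16-bit grayscale).
#' @return Integer matrix of object IDs.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) .stop2("mask file does not exist: ", path)
  depth <- png_bit_depth(path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  scale <- if (depth >= 16) 65535 else 255
  m <- as.integer(round(arr * scale))
  dim(m) <- dim(arr)
  m
}

#' Labelled connected components of a binary mask
#'
#' Thin wrapper over [EBImage::bwlabel()] (4-connectivity) returning a
#' plain integer matrix.
#' @noRd
label_components <- function(binary) {
  m <- EBImage::imageData(EBImage::bwlabel(binary * 1))
  storage.mode(m) <- "integer"
  m
}
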