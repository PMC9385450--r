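#' Canonical measurement column order
#'
#' The 21 per-comet features in table order: whole comet (6), head (7),
#' tail (8), preceded by `comet_id`, `image`, `class`.
#' @return Character vector of column names.
#' @export
feature_columns <- function() {
  c("comet_area", "comet_max_length", "comet_mean_intensity",
    "comet_std_intensity", "comet_sum_intensity", "comet_sphericity",
    "head_area", "head_max_length", "head_mean_intensity",
    "head_std_intensity", "head_sum_intensity", "head_sphericity",
    "head_percent_dna",
    "tail_area", "tail_max_length", "tail_mean_intensity",
    "tail_std_intensity", "tail_sum_intensity", "tail_percent_dna",
    "tail_extent_moment", "tail_olive_moment")
}

measurement_columns <- function(extra = character()) {
  c("comet_id", "image", "class", feature_columns(), extra)
}

#' Export comet measurements to CSV
#'
#' Writes one row per comet with columns `comet_id`, `image`, `class`
#' followed by the 21 features in table order (and any registered extra
#' features). Floats are written with 6 significant digits.
#'
#' @param records a data frame of feature records (rows from
#'   [comet_features()], possibly with `comet_id`, `image`, `class`
#'   columns) or a list of such single-row records.
#' @param path output CSV path.
#' @export
export_measurements <- function(records, path) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  extra <- setdiff(names(records), measurement_columns())
  cols <- measurement_columns(extra)
  if (is.null(records) || nrow(records) == 0) {
    warning("no comet records: writing header-only measurements file",
            call. = FALSE)
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                    cols))
    write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  for (col in c("comet_id", "image", "class"))
    if (is.null(records[[col]])) records[[col]] <- NA
  missing <- setdiff(feature_columns(), names(records))
  if (length(missing) > 0)
    .stop2("records lack feature columns: ", paste(missing, collapse = ", "))
  out <- records[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("comet_id", "class"))
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a measurements CSV written by [export_measurements()]
#'
#' @param path CSV path.
#' @return Data frame with one row per comet.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) .stop2("measurements file does not exist: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
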