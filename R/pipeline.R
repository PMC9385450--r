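#' Pipeline run configuration
#'
#' A fully serializable bundle of settings: the same config and seed on
#' the same inputs reproduces a run bit for bit.
#'
#' @param stain_mode `"fluorescent"` or `"silver"`.
#' @param settings [threshold_settings()] for the semi-automatic stage.
#' @param detector list of [detect_comets()] arguments for automatic ROI
#'   proposal.
#' @param classifier optional path to a saved classifier, or a
#'   `comet_classifier`, applied to the measured features.
#' @param features optional include-list of feature columns for the
#'   classifier.
#' @param mode `"auto"` (detect ROIs) or `"roi"` (caller supplies ROIs).
#' @param seed integer seed echoed into the log.
#' @param out_dir output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(stain_mode = "fluorescent",
                       settings = threshold_settings(),
                       detector = list(), classifier = NULL,
                       features = NULL, mode = c("auto", "roi"),
                       seed = 1, out_dir = "cometrics_out") {
  mode <- match.arg(mode)
  structure(list(stain_mode = stain_mode, settings = settings,
                 detector = detector, classifier = classifier,
                 features = features, mode = mode, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

config_as_json <- function(config) {
  jsonlite::toJSON(list(
    stain_mode = config$stain_mode,
    settings = unclass(config$settings),
    detector = config$detector,
    features = config$features,
    mode = config$mode,
    seed = config$seed
  ), auto_unbox = TRUE, digits = NA, null = "null")
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' For each image: read (with stain-aware ingestion), obtain ROIs
#' (automatic detection or caller-supplied), segment every comet, extract
#' the 21 features, and optionally classify. Writes per-image comet and
#' head label-mask PNGs, one combined measurements CSV, optional
#' predicted labels, a run log and a machine-readable manifest of every
#' output file. Per-image failures are logged and skipped; the function
#' errors only if every image fails.
#'
#' @param config a [run_config()].
#' @param images character vector of image paths, or a list of
#'   [comet_image()] objects.
#' @param rois optional list (one element per image) of lists of
#'   `comet_roi`, required when `config$mode == "roi"`.
#' @return Invisibly, a list with `measurements`, `masks` (paths) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, images, rois = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  cfg_json <- config_as_json(config)
  log_line(log_con, "cometrics ",
           as.character(utils::packageVersion("cometrics")),
           " | seed ", config$seed)
  log_line(log_con, "config ", cfg_json)
  if (config$mode == "roi" && is.null(rois))
    .stop2("mode 'roi' requires a list of ROIs per image")

  classifier <- config$classifier
  if (is.character(classifier)) classifier <- load_classifier(classifier)

  outputs <- character(0)
  records <- list()
  n_failed <- 0
  image_names <- if (is.character(images)) basename(images)
                 else sprintf("image_%03d", seq_along(images))
  for (i in seq_along(images)) {
    name <- image_names[i]
    res <- tryCatch({
      img <- if (is.character(images))
        read_comet_image(images[i], stain_mode = config$stain_mode)
      else ingest_image(images[[i]])
      img_rois <- if (config$mode == "auto")
        do.call(detect_comets, c(list(img), config$detector))
      else rois[[i]]
      log_line(log_con, name, ": ", length(img_rois), " ROIs")
      comet_lab <- matrix(0L, img$height, img$width)
      head_lab <- matrix(0L, img$height, img$width)
      recs <- list()
      for (k in seq_along(img_rois)) {
        seg <- tryCatch(
          segment_roi(img, img_rois[[k]], config$settings, comet_id = k),
          error = function(e) {
            log_line(log_con, name, ": comet ", k, " skipped: ",
                     conditionMessage(e))
            NULL
          })
        if (is.null(seg)) next
        comet_lab[seg$comet_mask] <- k
        head_lab[seg$head_mask] <- k
        rec <- comet_features(img, seg)
        rec$image <- name
        recs[[length(recs) + 1]] <- rec
      }
      stem <- tools::file_path_sans_ext(name)
      mask_files <- file.path(config$out_dir,
                              paste0(stem, c("_comet_mask.png",
                                             "_head_mask.png")))
      write_label_mask(comet_lab, mask_files[1])
      write_label_mask(head_lab, mask_files[2])
      outputs <- c(outputs, mask_files)
      records <- c(records, recs)
      TRUE
    }, error = function(e) {
      log_line(log_con, name, ": FAILED: ", conditionMessage(e))
      FALSE
    })
    if (!isTRUE(res)) n_failed <- n_failed + 1
  }
  if (n_failed == length(images))
    .stop2("all ", length(images), " images failed; see ", log_path)

  measurements <- if (length(records) > 0) do.call(rbind, records) else NULL
  if (!is.null(measurements) && !is.null(classifier)) {
    measurements$class <- predict(classifier, measurements)
    log_line(log_con, "classified ", nrow(measurements), " comets")
  }
  csv_path <- file.path(config$out_dir, "measurements.csv")
  export_measurements(measurements, csv_path)
  outputs <- c(outputs, csv_path)

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(version = as.character(utils::packageVersion("cometrics")),
         seed = config$seed,
         n_images = length(images), n_failed = n_failed,
         files = basename(c(outputs, log_path))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  log_line(log_con, "done: ", length(records), " comets, ",
           n_failed, " image failures")
  invisible(list(measurements = measurements, masks = outputs,
                 manifest = manifest_path,
                 status = if (n_failed > 0) 1L else 0L))
}
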