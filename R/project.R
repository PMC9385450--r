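PROJECT_FORMAT_VERSION <- "1.0"

#' Create an editable analysis project
#'
#' A project bundles image references, per-comet segmentations (ROIs,
#' threshold settings and masks), class labels and a feature cache, so an
#' analysis can be saved, shared and modified later.
#'
#' @param images named list; each element is `list(path=, stain_mode=)`.
#' @param segmentations list of [comet_segmentation] objects.
#' @param class_labels optional integer vector named by comet ID.
#' @param features optional cached measurements data frame.
#' @return An object of class `comet_project`.
#' @export
comet_project <- function(images = list(), segmentations = list(),
                          class_labels = NULL, features = NULL) {
  structure(list(
    format_version = PROJECT_FORMAT_VERSION,
    images = images,
    segmentations = segmentations,
    class_labels = class_labels,
    features = features
  ), class = "comet_project")
}

roi_to_json <- function(roi) {
  list(kind = roi$kind, geometry = lapply(roi$geometry, I_num))
}

I_num <- function(x) as.numeric(x)

json_to_roi <- function(j) {
  g <- j$geometry
  switch(j$kind,
    circle = roi_circle(center = as.numeric(unlist(g$center)),
                        radius = as.numeric(g$radius)),
    box = roi_box(rows = as.numeric(unlist(g$rows)),
                  cols = as.numeric(unlist(g$cols))),
    polygon = roi_polygon(vertices = matrix(as.numeric(unlist(g$vertices)),
                                            ncol = 2, byrow = TRUE)),
    .stop2("unknown ROI kind in project file: ", j$kind))
}

#' Save a project to a directory
#'
#' Writes a human-diffable `project.json` plus one sidecar label-mask PNG
#' per comet (pixel value 0 = background, 1 = tail, 2 = head). Saving,
#' loading and saving again produces byte-identical files.
#'
#' @param project a [comet_project()].
#' @param dir project directory (created if needed).
#' @export
save_project <- function(project, dir) {
  stopifnot(inherits(project, "comet_project"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  comets <- lapply(project$segmentations, function(seg) {
    mask_file <- sprintf("masks/comet_%04d.png", seg$comet_id)
    coded <- matrix(0L, nrow(seg$comet_mask), ncol(seg$comet_mask))
    coded[seg$tail_mask] <- 1L
    coded[seg$head_mask] <- 2L
    write_label_mask(coded, file.path(dir, mask_file))
    list(
      comet_id = seg$comet_id,
      image = seg$image %||% NA,
      roi = if (!is.null(seg$roi)) roi_to_json(seg$roi) else NULL,
      settings = unclass(seg$settings),
      class_label = unname(project$class_labels[as.character(seg$comet_id)]),
      mask_file = mask_file
    )
  })
  doc <- list(
    format_version = project$format_version,
    images = project$images,
    comets = comets,
    features = project$features
  )
  jsonlite::write_json(doc, file.path(dir, "project.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", null = "null", dataframe = "rows")
  invisible(dir)
}

#' Load a project saved by [save_project()]
#'
#' @param path project directory (or its `project.json`).
#' @return A [comet_project()].
#' @export
load_project <- function(path) {
  json_path <- if (dir.exists(path)) file.path(path, "project.json") else path
  dir <- dirname(json_path)
  if (!file.exists(json_path))
    .stop2("project file does not exist: ", json_path)
  doc <- tryCatch(
    jsonlite::read_json(json_path),
    error = function(e) .stop2("cannot parse project file '", json_path,
                               "': ", conditionMessage(e)))
  ver <- doc$format_version
  if (is.null(ver) || !identical(ver, PROJECT_FORMAT_VERSION))
    .stop2("project format version '", ver %||% "<missing>",
           "' does not match supported version '", PROJECT_FORMAT_VERSION,
           "'; please upgrade the project explicitly")
  labels <- integer(0)
  segs <- lapply(doc$comets, function(cj) {
    coded <- read_label_mask(file.path(dir, cj$mask_file))
    s <- cj$settings
    seg <- comet_segmentation(
      comet_mask = coded > 0L,
      head_mask = coded == 2L,
      roi = if (!is.null(cj$roi)) json_to_roi(cj$roi) else NULL,
      settings = threshold_settings(
        modality = s$modality,
        comet_scale = as.numeric(s$comet_scale),
        head_scale = as.numeric(s$head_scale),
        dilation_radius = as.numeric(s$dilation_radius)),
      comet_id = as.integer(cj$comet_id))
    seg$image <- if (is.null(cj$image) || is.na(cj$image[[1]])) NULL
                 else as.character(cj$image)
    if (!is.null(cj$class_label))
      labels[as.character(cj$comet_id)] <<- as.integer(cj$class_label)
    seg
  })
  features <- if (!is.null(doc$features))
    as.data.frame(do.call(rbind, lapply(doc$features, function(r)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v)))))
  else NULL
  comet_project(
    images = lapply(doc$images, function(im)
      list(path = im$path, stain_mode = im$stain_mode)),
    segmentations = segs,
    class_labels = if (length(labels) > 0) labels else NULL,
    features = features)
}
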