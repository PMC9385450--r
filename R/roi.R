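#' Regions of interest
#'
#' ROIs mark single comets for semi-automatic segmentation, mirroring a
#' user drawing a circle (or box/freehand polygon) around each comet.
#' Coordinates are 0-based `(row, col)` pixel positions.
#'
#' @param center numeric `(row, col)` of the circle center.
#' @param radius circle radius in pixels.
#' @return An object of class `comet_roi`.
#' @export
roi_circle <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(kind = "circle",
                 geometry = list(center = as.numeric(center),
                                 radius = as.numeric(radius))),
            class = "comet_roi")
}

#' @rdname roi_circle
#' @param rows,cols numeric `(min, max)` 0-based pixel ranges of the box.
#' @export
roi_box <- function(rows, cols) {
  stopifnot(length(rows) == 2, length(cols) == 2)
  structure(list(kind = "box",
                 geometry = list(rows = as.numeric(sort(rows)),
                                 cols = as.numeric(sort(cols)))),
            class = "comet_roi")
}

#' @rdname roi_circle
#' @param vertices n x 2 matrix of polygon vertices, 0-based `(row, col)`.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  structure(list(kind = "polygon",
                 geometry = list(vertices = unname(vertices))),
            class = "comet_roi")
}

# Even-odd interior test for pixel centers, vectorized over points.
points_in_polygon <- function(rows, cols, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(rows))
  j <- n
  for (i in seq_len(n)) {
    yi <- verts[i, 1]; xi <- verts[i, 2]
    yj <- verts[j, 1]; xj <- verts[j, 2]
    cross <- ((yi > rows) != (yj > rows)) &
      (cols < (xj - xi) * (rows - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# Pixels traversed by the polygon edges (boundary-inclusive rasterization).
polygon_edge_pixels <- function(verts, shape) {
  pts <- NULL
  n <- nrow(verts)
  for (i in seq_len(n)) {
    a <- verts[i, ]; b <- verts[if (i == n) 1 else i + 1, ]
    steps <- max(2, ceiling(2 * max(abs(b - a))) + 1)
    t <- seq(0, 1, length.out = steps)
    pts <- rbind(pts, cbind(round(a[1] + t * (b[1] - a[1])),
                            round(a[2] + t * (b[2] - a[2]))))
  }
  keep <- pts[, 1] >= 0 & pts[, 1] < shape[1] &
          pts[, 2] >= 0 & pts[, 2] < shape[2]
  unique(pts[keep, , drop = FALSE])
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
                         (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
   ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

polygon_is_simple <- function(verts) {
  n <- nrow(verts)
  edges <- lapply(seq_len(n), function(i)
    list(a = verts[i, ], b = verts[if (i == n) 1 else i + 1, ]))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # skip adjacent edges (shared vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(edges[[i]]$a, edges[[i]]$b,
                             edges[[j]]$a, edges[[j]]$b)) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize an ROI to a logical pixel mask
#'
#' @param roi a `comet_roi`.
#' @param shape `(height, width)` of the target image.
#' @return Logical matrix, boundary-inclusive.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "comet_roi"))
  h <- shape[1]; w <- shape[2]
  m <- matrix(FALSE, h, w)
  if (roi$kind == "circle") {
    ctr <- roi$geometry$center; rad <- roi$geometry$radius
    rows <- matrix(seq_len(h) - 1, h, w)
    cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    m <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= rad^2
  } else if (roi$kind == "box") {
    g <- roi$geometry
    r0 <- max(0, floor(g$rows[1])); r1 <- min(h - 1, ceiling(g$rows[2]))
    c0 <- max(0, floor(g$cols[1])); c1 <- min(w - 1, ceiling(g$cols[2]))
    if (r1 >= r0 && c1 >= c0)
      m[(r0:r1) + 1, (c0:c1) + 1] <- TRUE
  } else if (roi$kind == "polygon") {
    verts <- roi$geometry$vertices
    if (!polygon_is_simple(verts))
      .stop2("polygon ROI is self-intersecting")
    rr <- rep(seq_len(h) - 1, times = w)
    cc <- rep(seq_len(w) - 1, each = h)
    m <- matrix(points_in_polygon(rr, cc, verts), h, w)
    edge <- polygon_edge_pixels(verts, shape)
    if (nrow(edge) > 0) m[edge + 1] <- TRUE
  }
  if (!any(m)) .stop2("ROI lies entirely outside the image")
  m
}
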