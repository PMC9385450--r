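test_that("head and tail partition the comet exactly", {
  fix <- fixture_comet_image(tail_length = 50, tail_fraction = 0.4)
  for (mod in c("otsu", "triangle", "average")) {
    seg <- segment_roi(fix$image, fix$roi, threshold_settings(mod))
    expect_identical(seg$head_mask | seg$tail_mask, seg$comet_mask)
    expect_false(any(seg$head_mask & seg$tail_mask))
    # single connected component
    expect_equal(max(EBImage::bwlabel(seg$comet_mask * 1)), 1)
  }
})

test_that("an undamaged comet segments with an empty tail", {
  fix <- fixture_comet_image(head_radius = 12)   # class 1
  for (mod in c("otsu", "triangle", "average")) {
    seg <- segment_roi(fix$image, fix$roi, threshold_settings(mod))
    expect_false(any(seg$tail_mask))
    expect_identical(seg$head_mask, seg$comet_mask)
  }
})

test_that("a half-tail comet yields a tail on the tail side with accurate PercentDNA", {
  p <- comet_params(NULL, head_radius = 10, head_peak = 200,
                    tail_length = 75, tail_fraction = 0.5,
                    orientation = 0.5)
  r <- render_comet(p)
  px <- round(r$patch)
  img <- comet_image(px)
  roi <- roi_circle((dim(px) - 1) / 2, max(dim(px)) / 2)
  seg <- segment_roi(img, roi, threshold_settings("triangle"))
  # head centred on the rendered head
  hc <- which(seg$head_mask, arr.ind = TRUE)
  gt_hc <- which(r$head_mask, arr.ind = TRUE)
  expect_lt(sqrt(sum((colMeans(hc) - colMeans(gt_hc))^2)), 5)
  # tail pixels lie on the ground-truth tail side
  expect_gt(sum(seg$tail_mask & r$tail_mask) / sum(seg$tail_mask), 0.8)
  pdna <- comet_features(img, seg)$tail_percent_dna
  expect_true(abs(pdna - 50) <= 10)
})

test_that("threshold scaling and dilation act monotonically on comet area", {
  fix <- fixture_comet_image(tail_length = 40, tail_fraction = 0.3)
  area <- function(s) sum(segment_roi(fix$image, fix$roi, s)$comet_mask)
  a_10 <- area(threshold_settings("triangle", comet_scale = 1.0))
  a_12 <- area(threshold_settings("triangle", comet_scale = 1.2))
  a_08 <- area(threshold_settings("triangle", comet_scale = 0.8))
  expect_lte(a_12, a_10)
  expect_gte(a_08, a_10)
  d_2 <- area(threshold_settings("triangle", dilation_radius = 2))
  d_5 <- area(threshold_settings("triangle", dilation_radius = 5))
  expect_gte(d_2, a_10)
  expect_gte(d_5, d_2)
  # dilation happens before the split, so the partition still holds
  seg <- segment_roi(fix$image, fix$roi,
                     threshold_settings("triangle", dilation_radius = 3))
  expect_identical(seg$head_mask | seg$tail_mask, seg$comet_mask)
})

test_that("empty ROIs raise an empty-segmentation error", {
  fix <- fixture_comet_image()
  dark <- comet_image(fix$image$pixels * 0 +
                        matrix(sample(9:11, length(fix$image$pixels),
                                      TRUE), nrow(fix$image$pixels)))
  expect_error(
    segment_roi(dark, roi_circle(c(5, 5), 4),
                threshold_settings("otsu", comet_scale = 50)),
    "empty segmentation")
  expect_error(rasterize_roi(roi_circle(c(-100, -100), 3), c(40, 40)),
               "outside")
})

test_that("manual contours rasterize boundary-inclusively", {
  img <- fixture_comet_image(head_radius = 10)$image
  # axis-aligned 10x10 square: 100 pixels including the boundary
  sq <- rbind(c(20, 20), c(20, 29), c(29, 29), c(29, 20))
  m <- rasterize_roi(roi_polygon(sq), dim(img$pixels))
  expect_equal(sum(m), 100)

  # triangle: boundary-inclusive count exceeds the analytic area by at
  # most about half the perimeter
  tri <- rbind(c(5, 5), c(5, 45), c(35, 25))
  mt <- rasterize_roi(roi_polygon(tri), dim(img$pixels))
  analytic <- abs((45 - 5) * (35 - 5)) / 2
  perim <- 40 + 2 * sqrt(30^2 + 20^2)
  expect_gte(sum(mt), analytic)
  expect_lt(sum(mt) - analytic, perim / 2 + 10)

  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1))), ">= 3")
  bow <- rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0))
  expect_error(rasterize_roi(roi_polygon(bow), c(40, 40)),
               "self-intersecting")
})

test_that("contours over pure background are rejected, over comets accepted", {
  fix <- fixture_comet_image(head_radius = 10, pad = 30)
  poly_bg <- rbind(c(2, 2), c(2, 12), c(12, 12), c(12, 2))
  expect_error(rasterize_contour(poly_bg, fix$image), "no foreground")
  ctr <- which(fix$head_mask, arr.ind = TRUE)
  cm <- colMeans(ctr)
  poly_fg <- rbind(cm + c(-15, -15), cm + c(-15, 15), cm + c(15, 15),
                   cm + c(15, -15))
  seg <- rasterize_contour(poly_fg, fix$image)
  expect_equal(sum(seg$comet_mask), 31 * 31)
  expect_true(any(seg$head_mask))
  expect_identical(seg$head_mask | seg$tail_mask, seg$comet_mask)
})

test_that("automatic detection proposes one ROI per well-separated comet", {
  ds <- generate_dataset(1, comets_per_image = c(30, 30),
                         image_shape = c(900, 1200), seed = 21)[[1]]
  img <- ingest_image(ds$image)
  rois <- detect_comets(img)
  centers <- cbind(ds$params$center_row, ds$params$center_col)
  # count ROIs containing exactly one ground-truth comet center
  hits <- vapply(rois, function(roi) {
    d2 <- (centers[, 1] - roi$geometry$center[1])^2 +
      (centers[, 2] - roi$geometry$center[2])^2
    sum(d2 <= roi$geometry$radius^2)
  }, numeric(1))
  expect_gte(sum(hits == 1), 27)
})

test_that("blank images and border comets are filtered by the detector", {
  blank <- comet_image(matrix(10, 120, 120))
  expect_length(detect_comets(blank), 0)

  px <- matrix(10, 120, 120)
  px[1:15, 40:60] <- 200     # touches row 1
  px[60:80, 60:80] <- 200    # interior
  img <- comet_image(px)
  rois <- detect_comets(img, min_area = 50)
  expect_length(rois, 1)
  expect_true(abs(rois[[1]]$geometry$center[1] - 69) < 3)
  rois_all <- detect_comets(img, min_area = 50, exclude_border = FALSE)
  expect_length(rois_all, 2)
})
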