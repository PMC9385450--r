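test_that("basic region features are exact on constructed shapes", {
  px <- matrix(0, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[5:9, 5:9] <- TRUE        # 5x5 square
  px[mask] <- 10
  f <- region_basic_features(px, mask)
  expect_equal(f$area, 25)
  expect_equal(f$mean_intensity, 10)
  expect_equal(f$std_intensity, 0)
  expect_equal(f$sum_intensity, 250)

  # 30-pixel horizontal line: max length 30 +- 1 px discretization
  line <- matrix(FALSE, 10, 40); line[5, 6:35] <- TRUE
  lpx <- matrix(1, 10, 40)
  fl <- region_basic_features(lpx, line)
  expect_true(abs(fl$max_length - 30) <= 1)

  # random blob: mean x area == sum exactly
  withr::local_seed(8)
  blob <- matrix(runif(400) < 0.4, 20, 20)
  bpx <- matrix(sample(1:255, 400, TRUE), 20, 20)
  fb <- region_basic_features(bpx, blob)
  expect_equal(fb$mean_intensity * fb$area, fb$sum_intensity)
  expect_equal(fb$sum_intensity, sum(bpx[blob]))

  expect_error(region_basic_features(matrix(0, 3, 3), matrix(TRUE, 2, 2)),
               "shape")
})

test_that("sphericity matches closed forms and is clamped to [0, 1]", {
  r <- 7.3
  expect_equal(sphericity(pi * r^2, 2 * pi * r), 1)
  s <- 12
  expect_equal(sphericity(s^2, 4 * s), sqrt(pi) / 2, tolerance = 1e-12)
  expect_error(sphericity(10, 0), "perimeter")

  # rasterized disc, radius 20, with the package's perimeter estimator
  rows <- matrix(1:51, 51, 51); cols <- t(rows)
  disc <- (rows - 26)^2 + (cols - 26)^2 <= 20^2
  val <- sphericity(sum(disc), perimeter_estimate(disc))
  expect_gte(val, 0.9); expect_lte(val, 1)
})

test_that("a tailless comet records zero tail features and 100% head DNA", {
  fix <- fixture_comet_image()
  seg <- comet_segmentation(fix$comet_mask, fix$head_mask)
  f <- comet_features(fix$image, seg)
  expect_equal(f$tail_area, 0)
  expect_equal(f$tail_extent_moment, 0)
  expect_equal(f$tail_olive_moment, 0)
  expect_equal(f$tail_percent_dna, 0)
  expect_equal(f$head_percent_dna, 100)
})

test_that("the Olive moment follows its definition on constructed masks", {
  px <- matrix(0, 30, 30)
  head <- matrix(FALSE, 30, 30); head[11, 11] <- TRUE   # centroid (10,10)
  tail <- matrix(FALSE, 30, 30); tail[14, 15] <- TRUE   # centroid (13,14)
  px[head] <- 80; px[tail] <- 80                        # tail sum / total = 0.5
  seg <- comet_segmentation(head | tail, head)
  f <- comet_features(px, seg)
  expect_equal(f$tail_olive_moment, 5 * 0.5)            # distance 5 x 0.5
  expect_equal(f$tail_percent_dna, 50)
  expect_equal(f$tail_extent_moment, f$tail_max_length * 0.5)
})

test_that("PercentDNA and intensity sums respect the mask partition", {
  fix <- fixture_comet_image(tail_length = 60, tail_fraction = 0.4)
  seg <- comet_segmentation(fix$comet_mask, fix$head_mask)
  f <- comet_features(fix$image, seg)
  expect_equal(f$head_percent_dna + f$tail_percent_dna, 100)
  expect_equal(f$head_sum_intensity + f$tail_sum_intensity,
               f$comet_sum_intensity)
  expect_equal(f$comet_area, f$head_area + f$tail_area)
  expect_equal(f$tail_extent_moment,
               f$tail_max_length * f$tail_percent_dna / 100)
})

test_that("ground-truth masks recover the generator's tail fraction", {
  p <- comet_params(NULL, head_radius = 10, head_peak = 200,
                    tail_length = 66, tail_fraction = 0.4,
                    orientation = 2.2)
  r <- render_comet(p)
  seg <- comet_segmentation(r$comet_mask, r$head_mask)
  f <- comet_features(round(r$patch), seg)
  expect_true(abs(f$tail_percent_dna - 40) <= 1.5)
})

test_that("features are invariant under image translation", {
  p <- comet_params(NULL, head_radius = 9, head_peak = 180,
                    tail_length = 45, tail_fraction = 0.35,
                    orientation = 1.0)
  r <- render_comet(p)
  ph <- nrow(r$patch); pw <- ncol(r$patch)
  embed <- function(dr, dc) {
    px <- matrix(0, ph + 40, pw + 40)
    px[dr + seq_len(ph), dc + seq_len(pw)] <- round(r$patch)
    m <- function(x) {
      y <- matrix(FALSE, ph + 40, pw + 40)
      y[dr + seq_len(ph), dc + seq_len(pw)] <- x; y
    }
    comet_features(px, comet_segmentation(m(r$comet_mask), m(r$head_mask)))
  }
  f1 <- embed(3, 5); f2 <- embed(25, 17)
  expect_equal(f1, f2)
})

test_that("user-defined features register, export and handle bad values", {
  withr::defer(clear_registered_features())
  clear_registered_features()
  register_feature("tail_to_head_area_ratio",
                   function(px, comet, head, tail) sum(tail) / sum(head))
  expect_error(register_feature("tail_to_head_area_ratio", identity),
               "already registered")
  fix <- fixture_comet_image(tail_length = 40, tail_fraction = 0.3)
  seg <- comet_segmentation(fix$comet_mask, fix$head_mask)
  f <- comet_features(fix$image, seg)
  expect_true("tail_to_head_area_ratio" %in% names(f))
  expect_equal(f$tail_to_head_area_ratio,
               sum(fix$tail_mask) / sum(fix$head_mask))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_measurements(f, csv)
  expect_true("tail_to_head_area_ratio" %in% names(read_measurements(csv)))

  register_feature("broken", function(px, comet, head, tail) NaN)
  expect_warning(f2 <- comet_features(fix$image, seg), "non-finite")
  expect_true(is.na(f2$broken))
})
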