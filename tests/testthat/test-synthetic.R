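test_that("rendering is deterministic and respects the head/tail geometry", {
  p <- comet_params(NULL, head_radius = 10, head_peak = 200,
                    tail_length = 40, tail_fraction = 0.3,
                    orientation = 1.1)
  r1 <- render_comet(p)
  r2 <- render_comet(p)
  expect_identical(r1, r2)
  expect_true(all(!(r1$head_mask & r1$tail_mask)))
  expect_identical(r1$comet_mask, r1$head_mask | r1$tail_mask)

  r0 <- render_comet(comet_params(NULL, head_radius = 8, head_peak = 180))
  expect_false(any(r0$tail_mask))
  expect_equal(r0$achieved_tail_fraction, 0)
})

test_that("integrated tail intensity matches the requested fraction", {
  for (tf in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    p <- comet_params(NULL, head_radius = 10, head_peak = 200,
                      tail_length = round(30 + 90 * tf),
                      tail_fraction = tf, orientation = 0.4)
    r <- render_comet(p)
    measured <- sum(r$patch[r$tail_mask]) / sum(r$patch[r$comet_mask])
    expect_true(abs(measured - tf) <= 0.01,
                label = sprintf("tail fraction %.2f achieved %.4f", tf,
                                measured))
    expect_equal(r$achieved_tail_fraction, measured)
  }
})

test_that("invalid comet parameters are rejected", {
  expect_error(comet_params(NULL, 10, 200, tail_length = 0,
                            tail_fraction = 0.2), "if and only if")
  expect_error(comet_params(NULL, 10, 200, tail_length = 20,
                            tail_fraction = 0), "if and only if")
  expect_error(comet_params(NULL, 10, 200, tail_length = 20,
                            tail_fraction = 1), "0.99")
  p <- comet_params(c(2, 2), head_radius = 10, head_peak = 200)
  expect_error(render_comet(p, patch_shape = c(30, 30)), "fit")
})

test_that("the class map bins tail fractions monotonically", {
  expect_identical(class_from_tail_fraction(c(0, 0.04, 0.05, 0.24, 0.3,
                                              0.5, 0.79, 0.8, 1)),
                   c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L))
  tf <- sort(runif(50))
  expect_true(!is.unsorted(class_from_tail_fraction(tf)))
})

test_that("generated datasets are seeded, in-range and stain-consistent", {
  ds <- generate_dataset(2, comets_per_image = c(5, 9),
                         image_shape = c(300, 380), seed = 7)
  expect_length(ds, 2)
  for (d in ds) {
    n <- nrow(d$params)
    expect_true(n >= 5 && n <= 9)
    expect_setequal(setdiff(unique(as.vector(d$comet_mask)), 0L),
                    seq_len(n))
    # head mask is contained in the comet mask, ID by ID
    expect_true(all(d$comet_mask[d$head_mask > 0] ==
                      d$head_mask[d$head_mask > 0]))
  }
  ds2 <- generate_dataset(2, comets_per_image = c(5, 9),
                          image_shape = c(300, 380), seed = 7)
  expect_identical(ds, ds2)

  silver <- generate_dataset(1, comets_per_image = c(3, 3),
                             image_shape = c(200, 260),
                             stain_mode = "silver", seed = 3)[[1]]
  comet_px <- silver$comet_mask > 0
  # as acquired: comets darker than background
  expect_lt(mean(silver$image$pixels[comet_px]),
            mean(silver$image$pixels[!comet_px]))
  bright <- ingest_image(silver$image)
  expect_gt(mean(bright$pixels[comet_px]), mean(bright$pixels[!comet_px]))
})

test_that("an all-class-1 mix renders no tails", {
  ds <- generate_dataset(1, comets_per_image = c(4, 4),
                         class_mix = c(1, 0, 0, 0, 0),
                         image_shape = c(200, 260), seed = 5)[[1]]
  expect_true(all(ds$tail_mask == 0L))
  expect_true(all(ds$params$class_label == 1L))
})

test_that("ground-truth PercentDNA matches the requested tail fraction", {
  ds <- generate_dataset(1, comets_per_image = c(8, 8),
                         noise = list(gaussian_sd = 0,
                                      background_level = 0),
                         image_shape = c(400, 500), seed = 13)[[1]]
  img <- ingest_image(ds$image)
  for (i in seq_len(nrow(ds$params))) {
    seg <- comet_segmentation(ds$comet_mask == i, ds$head_mask == i,
                              comet_id = i)
    pdna <- comet_features(img, seg)$tail_percent_dna
    expect_true(abs(pdna - 100 * ds$params$tail_fraction[i]) <= 1,
                label = sprintf("comet %d: pdna %.2f vs %.2f", i, pdna,
                                100 * ds$params$tail_fraction[i]))
  }
})

test_that("impossible densities raise a placement error", {
  expect_error(
    generate_dataset(1, comets_per_image = c(40, 40),
                     image_shape = c(120, 120), seed = 1),
    "place")
})

test_that("datasets write to disk with images, masks and parameters", {
  d <- withr::local_tempdir()
  ds <- generate_dataset(1, comets_per_image = c(3, 3),
                         image_shape = c(200, 260), seed = 9)
  write_dataset(ds, d)
  expect_true(file.exists(file.path(d, "image_001.tif")))
  mask <- read_label_mask(file.path(d, "image_001_comet_mask.png"))
  expect_identical(mask, ds[[1]]$comet_mask)
  par <- read.csv(file.path(d, "image_001_params.csv"))
  expect_equal(nrow(par), 3)
  img <- read_comet_image(file.path(d, "image_001.tif"), "fluorescent")
  expect_equal(img$pixels, ds[[1]]$image$pixels, ignore_attr = TRUE)
})
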