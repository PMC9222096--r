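test_that("integer images round-trip bit-exactly through PNG and TIFF", {
  set.seed(11)
  px8 <- matrix(sample(0:255, 40 * 30, replace = TRUE), 40, 30)
  px16 <- matrix(sample(0:65535, 40 * 30, replace = TRUE), 40, 30)
  f8 <- withr::local_tempfile(fileext = ".png")
  f16t <- withr::local_tempfile(fileext = ".tif")
  write_image(mammogram_image(px8, bit_depth = 8L), f8)
  write_image(mammogram_image(px16, bit_depth = 16L), f16t)
  expect_identical(read_image(f8)$pixels, px8 + 0)
  expect_identical(read_image(f16t)$pixels, px16 + 0)
  # PNG output is 8-bit only; deeper data goes to TIFF
  expect_error(write_image(mammogram_image(px16, bit_depth = 16L),
                           withr::local_tempfile(fileext = ".png")),
               class = "calcgraph_format_error")
  # constant zero image stays all-zero
  fz <- withr::local_tempfile(fileext = ".png")
  write_image(mammogram_image(matrix(0, 5, 5), bit_depth = 8L), fz)
  expect_true(all(read_image(fz)$pixels == 0))
})

test_that("MONOCHROME1 DICOM intensities are inverted against bits stored", {
  set.seed(7)
  px <- matrix(sample(0:4095, 24 * 16, replace = TRUE), 24, 16)
  f1 <- withr::local_tempfile(fileext = ".dcm")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  calcgraph:::write_minimal_dicom(px, f1, photometric = "MONOCHROME1",
                                  bits_stored = 12L, view = "CC")
  calcgraph:::write_minimal_dicom(px, f2, photometric = "MONOCHROME2",
                                  bits_stored = 12L)
  inv <- read_image(f1, format = "dicom")
  raw <- read_image(f2, format = "dicom")
  expect_identical(inv$pixels, (2^12 - 1) - px + 0)
  expect_identical(raw$pixels, px + 0)
  expect_identical(inv$view, "CC")
  expect_identical(inv$bit_depth, 12L)
})

test_that("colour and unreadable inputs are rejected with format errors", {
  fc <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(10 * 10 * 3), c(10, 10, 3)), fc)
  expect_error(read_image(fc), class = "calcgraph_format_error")
  fbad <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", fbad)
  expect_error(read_image(fbad), class = "calcgraph_format_error")
})

test_that("breast segmentation recovers a half-ellipse phantom", {
  spec <- pattern_spec("diffuse", n_spots = 0, noise_sigma = 0.01, seed = 5)
  ph <- generate_phantom(spec)
  bm <- segment_breast(ph$image)
  iou <- sum(bm$mask & ph$mask) / sum(bm$mask | ph$mask)
  expect_gte(iou, 0.95)
  expect_gt(bm$area_fraction, 0)
  expect_lt(bm$area_fraction, 1)
  # exactly one 8-connected component
  lab <- calcgraph:::.cg_label_components(
    matrix(as.integer(bm$mask), nrow(bm$mask)), 8L)
  expect_identical(max(lab), 1L)
  # idempotence: segmenting the masked image reproduces the mask
  masked <- mammogram_image(ph$image$pixels * bm$mask)
  expect_identical(segment_breast(masked)$mask, bm$mask)
})

test_that("segmentation keeps only the largest blob and matches Otsu oracle", {
  img <- matrix(10, 64, 64)
  img[5:9, 5:9] <- 200                 # small blob (25 px)
  img[20:49, 20:49] <- 200             # large blob (900 px)
  bm <- segment_breast(mammogram_image(img, bit_depth = 8L))
  expect_true(all(bm$mask[20:49, 20:49]))
  expect_false(any(bm$mask[5:9, 5:9]))
  # brute-force Otsu over all 256 thresholds on the bimodal image
  counts <- tabulate(img + 1L, nbins = 256L)
  lvl <- 0:255
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    w0 <- sum(counts[lvl <= t]); w1 <- sum(counts[lvl > t])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(lvl[lvl <= t] * counts[lvl <= t]) / w0
    m1 <- sum(lvl[lvl > t] * counts[lvl > t]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- t }
  }
  expect_gt(bm$threshold, 10)
  expect_lt(bm$threshold, 200)
  expect_gt(best_t, 10 - 1e-9)
  expect_lt(best_t, 200)
  # the mask equals the 200-valued region minus the dropped smaller blob
  expected <- img == 200
  expected[5:9, 5:9] <- FALSE
  expect_identical(unname(bm$mask), unname(expected))
})

test_that("constant images raise a degenerate-input error", {
  expect_error(segment_breast(mammogram_image(matrix(5, 10, 10))),
               class = "calcgraph_degenerate_error")
})

test_that("annotations round-trip through JSON", {
  ann <- list(structure(list(image_id = "img1",
                             geometry = list(type = "circle",
                                             cx = 30, cy = 40, r = 10),
                             label = factor("grouped",
                                            levels = calc_classes())),
                        class = "roi_annotation"))
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_identical(as.character(back[[1]]$label), "grouped")
  expect_identical(back[[1]]$image_id, "img1")
  expect_error(
    read_annotations({
      jsonlite::write_json(list(list(image_id = "x",
                                     geometry = list(type = "circle"),
                                     label = "spiral")), f,
                           auto_unbox = TRUE)
      f
    }),
    class = "calcgraph_input_error")
})
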