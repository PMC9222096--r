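test_that("top-hat response has the analytic values on constructed inputs", {
  # constant image: opening of a constant is itself
  expect_true(all(top_hat_transform(matrix(7, 20, 20), 2) == 0))
  # single bright pixel: full response at that pixel only
  img <- matrix(0, 21, 21); img[11, 11] <- 100
  th <- top_hat_transform(img, 2)
  expect_equal(th[11, 11], 100)
  expect_true(all(th[-c(21 * 10 + 11)] == 0))
  # plateau strictly larger than the SE: zero response in the interior
  img2 <- matrix(0, 30, 30); img2[8:24, 8:24] <- 50
  th2 <- top_hat_transform(img2, 3)
  expect_true(all(th2[11:21, 11:21] == 0))
})

test_that("top-hat is bounded by [0, I] and translation-equivariant", {
  set.seed(21)
  img <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
  th <- top_hat_transform(img, 3)
  expect_true(all(th >= 0))
  expect_true(all(th <= img))
  # interior equivariance under translation by (2, 3)
  shifted <- matrix(0, 40, 40)
  shifted[3:40, 4:40] <- img[1:38, 1:37]
  th_s <- top_hat_transform(shifted, 3)
  core <- 8:30
  expect_equal(th_s[core + 2, core + 3], th[core, core])
})

test_that("thresholding follows the fixed and percentile rules", {
  resp <- matrix(c(0, 5, 10, 0, 5, 10, 0, 5, 10), 3, 3)
  mask <- matrix(TRUE, 3, 3)
  det <- threshold_detect(resp, mask,
                          detection_config(threshold = list(fixed = 7)))
  expect_identical(unname(det == TRUE), unname(resp == 10))
  # all-zero response with positive fixed threshold: empty mask
  expect_false(any(threshold_detect(matrix(0, 3, 3), mask,
                                    detection_config(threshold = list(fixed = 1)))))
  # percentile rule against a sort-based oracle
  set.seed(3)
  r2 <- matrix(runif(50 * 50), 50, 50)
  m2 <- matrix(TRUE, 50, 50)
  det2 <- threshold_detect(r2, m2,
                           detection_config(threshold = list(percentile = 99)))
  cut <- quantile(sort(as.numeric(r2)), 0.99, type = 7)
  expect_identical(sum(det2), sum(r2 >= cut))
  # empty mask errors
  expect_error(threshold_detect(r2, matrix(FALSE, 50, 50)),
               class = "calcgraph_degenerate_error")
})

test_that("candidate extraction applies area bounds, centroids and ordering", {
  det <- matrix(FALSE, 30, 30)
  det[10:11, 10:11] <- TRUE             # area 4
  det[20, 25] <- TRUE                   # area 1
  img <- matrix(1, 30, 30)
  cfg <- detection_config(min_blob_area = 2, max_blob_area = 50)
  cands <- extract_candidates(det, img, cfg)
  expect_length(cands, 1L)
  # uniform weights over a 2x2 blob at rows/cols 10:11 -> centroid
  # (0-based) at 9.5, rounded to 10
  expect_equal(unname(cands[[1]]$center), c(10, 10))
  expect_identical(dim(cands[[1]]$patch), c(14L, 14L))
  # ordering is by (y, x)
  det2 <- matrix(FALSE, 30, 30)
  det2[5:6, 20:21] <- TRUE
  det2[5:6, 3:4] <- TRUE
  det2[25:26, 10:11] <- TRUE
  cands2 <- extract_candidates(det2, img, cfg)
  ys <- vapply(cands2, function(c) c$center[["y"]], 0)
  xs <- vapply(cands2, function(c) c$center[["x"]], 0)
  expect_true(!is.unsorted(ys))
  expect_identical(xs[1:2], sort(xs[1:2]))
})

test_that("planted phantom spots are recovered within one pixel", {
  spec <- pattern_spec("regional", n_spots = 25, seed = 31)
  ph <- generate_phantom(spec)
  cands <- detect_calcifications(ph$image, mask = segment_breast(ph$image))
  cc <- t(vapply(cands, `[[`, numeric(2), "center"))
  dmat <- sqrt(outer(ph$spots$x, cc[, 1], `-`)^2 +
                 outer(ph$spots$y, cc[, 2], `-`)^2)
  matched <- apply(dmat, 1, min)
  # spots overlapping a neighbour can merge into one blob, so a few may go
  # undetected; every detected spot must be localized to about a pixel
  expect_gte(mean(matched <= 4), 0.85)
  expect_true(all(matched[matched <= 4] <= 1.5))
})

test_that("verifier loss matches the cross-entropy formula", {
  expect_equal(verifier_loss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  expect_lt(verifier_loss(c(1 - 1e-12, 1e-12), c(1, 0)), 1e-9)
  set.seed(9)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  expect_equal(verifier_loss(p, y),
               mean(-(y * log(p) + (1 - y) * log(1 - p))))
})

test_that("verifier separates bright-spot patches from flat noise", {
  set.seed(17)
  make_patch <- function(pos) {
    p <- matrix(rnorm(14 * 14, 0.3, 0.03), 14, 14)
    if (pos) {
      g <- exp(-(outer((1:14 - 8)^2, (1:14 - 8)^2, `+`)) / (2 * 1.5^2))
      p <- p + 0.3 * g
    }
    p
  }
  n <- 60
  patches <- c(lapply(seq_len(n), function(i) make_patch(TRUE)),
               lapply(seq_len(n), function(i) make_patch(FALSE)))
  y <- rep(c(1, 0), each = n)
  hold <- c(1:10, n + 1:10)
  model <- train_verifier(patches[-hold], y[-hold], epochs = 100, seed = 2)
  acc <- mean((predict_verifier(model, patches[hold]) >= 0.5) == y[hold])
  expect_gte(acc, 0.95)
  expect_lt(tail(model$training$loss_history, 1),
            model$training$loss_history[1])
  # single-class training set errors
  expect_error(train_verifier(patches[1:5], rep(1, 5)),
               class = "calcgraph_degenerate_error")
})

test_that("candidate filtering respects the cutoff and preserves order", {
  spec <- pattern_spec("grouped", n_spots = 12, seed = 4)
  ph <- generate_phantom(spec)
  cands <- detect_calcifications(ph$image)
  expect_gte(length(cands), 3L)
  set.seed(1)
  pos <- lapply(cands, `[[`, "patch")
  neg <- lapply(seq_along(cands), function(i)
    matrix(rnorm(196, 0.3, 0.02), 14, 14))
  model <- train_verifier(c(pos, neg), rep(c(1, 0), each = length(cands)),
                          epochs = 60, seed = 3)
  kept_all <- filter_candidates(cands, model, cutoff = 0)
  expect_length(kept_all, length(cands))
  expect_true(all(vapply(kept_all, `[[`, 0, "verifier_prob") >= 0))
  kept_one <- filter_candidates(cands, model, cutoff = 1)
  expect_lte(length(kept_one), length(cands))
  kept <- filter_candidates(cands, model, cutoff = 0.5)
  probs <- vapply(kept, `[[`, 0, "verifier_prob")
  expect_true(all(probs >= 0.5))
  # order preserved: y non-decreasing as produced by extract_candidates
  ys <- vapply(kept, function(c) c$center[["y"]], 0)
  expect_true(!is.unsorted(ys))
})
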