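# Grayscale morphology with a disk structuring element. Border handling uses
# the "ignore outside" convention (erosion pads with +Inf, dilation with
# -Inf), which keeps the opening anti-extensive: opening(I) <= I pointwise,
# hence the white top-hat response lies in [0, I].

#' Disk structuring element
#'
#' @param radius Radius in pixels (>= 1).
#' @return Logical matrix of size `(2 * radius + 1)^2` marking the disk.
#' @export
disk_se <- function(radius) {
  assert_that(radius >= 1, "se radius must be >= 1")
  d <- 2L * as.integer(radius) + 1L
  off <- seq_len(d) - radius - 1L
  outer(off, off, function(a, b) a^2 + b^2 <= radius^2)
}

se_offsets <- function(se) {
  r <- (nrow(se) - 1L) %/% 2L
  idx <- which(se, arr.ind = TRUE)
  cbind(dy = idx[, 1L] - r - 1L, dx = idx[, 2L] - r - 1L)
}

# shift-and-reduce grayscale morphology
morph_reduce <- function(img, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  pad_val <- if (op == "erode") Inf else -Inf
  nr <- nrow(img); nc <- ncol(img)
  r <- max(abs(offsets))
  padded <- matrix(pad_val, nr + 2L * r, nc + 2L * r)
  padded[r + seq_len(nr), r + seq_len(nc)] <- img
  out <- matrix(pad_val, nr, nc)
  f <- if (op == "erode") pmin else pmax
  for (k in seq_len(nrow(offsets))) {
    out <- f(out, padded[r + offsets[k, 1L] + seq_len(nr),
                         r + offsets[k, 2L] + seq_len(nc)])
  }
  out
}

gray_erode <- function(img, se) morph_reduce(img, se_offsets(se), "erode")
gray_dilate <- function(img, se) morph_reduce(img, se_offsets(se), "dilate")
gray_open <- function(img, se) gray_dilate(gray_erode(img, se), se)
gray_close <- function(img, se) gray_erode(gray_dilate(img, se), se)

#' White top-hat transform
#'
#' Computes `I - opening(I, SE)` with a disk structuring element, where the
#' opening is erosion followed by dilation. The response extracts bright
#' structures smaller than the disk against an uneven background and is
#' pointwise bounded by `0 <= response <= I`.
#'
#' @param image A [mammogram_image()] or numeric matrix.
#' @param se_radius Disk radius in pixels.
#' @return Numeric matrix of the same shape as the image.
#' @export
top_hat_transform <- function(image, se_radius = 3L) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  assert_that(is.matrix(px), "image must be a matrix or mammogram_image")
  assert_that(se_radius >= 1, "se_radius must be >= 1",
              class = "calcgraph_config_error")
  assert_that(2 * se_radius < min(dim(px)),
              "se_radius too large for image dimensions",
              class = "calcgraph_config_error")
  px - gray_open(px, disk_se(se_radius))
}

#' Black bottom-hat transform
#'
#' `closing(I, SE) - I`; extracts dark structures smaller than the disk.
#' Used only by the optional contrast-enhancement mode.
#'
#' @inheritParams top_hat_transform
#' @return Numeric matrix.
#' @export
bottom_hat_transform <- function(image, se_radius = 3L) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  assert_that(se_radius >= 1, "se_radius must be >= 1",
              class = "calcgraph_config_error")
  gray_close(px, disk_se(se_radius)) - px
}

#' Morphological contrast enhancement (optional mode)
#'
#' `I + tophat(I) - bottomhat(I)`. Off by default in the detection pipeline;
#' the detector itself thresholds the plain white top-hat response.
#'
#' @inheritParams top_hat_transform
#' @return Numeric matrix.
#' @export
enhance_contrast <- function(image, se_radius = 3L) {
  px <- if (inherits(image, "mammogram_image")) image$pixels else image
  px + top_hat_transform(px, se_radius) - bottom_hat_transform(px, se_radius)
}
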