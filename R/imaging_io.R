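#' Construct a mammogram image object
#'
#' Wraps a 2D intensity matrix with optional acquisition metadata. The pixel
#' matrix is stored row-by-column (`pixels[row, col]`); all user-facing
#' coordinates in the package are `(x, y) = (column, row)`, 0-based, with the
#' origin at the top-left corner.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_spacing Optional pixel spacing in mm/px.
#' @param view Optional view tag (`"CC"` or `"MLO"`).
#' @param laterality Optional laterality (`"L"` or `"R"`).
#' @param source_id Identifier string (defaults to `"unknown"`).
#' @param bit_depth Bit depth of the source data (`NA` for unit-scaled float).
#'
#' @return An object of class `mammogram_image`.
#' @export
mammogram_image <- function(pixels, pixel_spacing = NULL, view = NULL,
                            laterality = NULL, source_id = "unknown",
                            bit_depth = NA_integer_) {
  assert_that(is.matrix(pixels) && length(pixels) > 0,
              "pixels must be a non-empty 2D matrix")
  assert_that(all(is.finite(pixels)) && all(pixels >= 0),
              "pixel intensities must be finite and non-negative")
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing, view = view,
                 laterality = laterality, source_id = source_id,
                 bit_depth = bit_depth),
            class = "mammogram_image")
}

#' @export
print.mammogram_image <- function(x, ...) {
  cat(sprintf("<mammogram_image> %s: %d x %d px, range [%.4g, %.4g]\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.mammogram_image <- function(x) dim(x$pixels)

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  assert_that(length(hdr) >= 25L &&
                identical(hdr[2:4], as.raw(c(0x50, 0x4e, 0x47))),
              "not a PNG file: ", path, class = "calcgraph_format_error")
  as.integer(hdr[25L])
}

#' Read a mammographic image
#'
#' Reads a single-frame grayscale PNG, TIFF or DICOM image. Integer formats
#' are preserved losslessly as integer-valued intensities (set
#' `normalize = TRUE` to linearly rescale to \[0, 1\]). For DICOM with
#' photometric interpretation MONOCHROME1, intensities are inverted as
#' `(2^bits_stored - 1) - p` so that higher always means brighter. Colour or
#' multi-frame inputs are rejected rather than converted.
#'
#' @param path Path to the image file.
#' @param format One of `"png"`, `"tiff"`, `"dicom"`; guessed from the file
#'   extension when `NULL`.
#' @param normalize Scale integer intensities to \[0, 1\]?
#'
#' @return A [mammogram_image()].
#' @export
read_image <- function(path, format = NULL, normalize = FALSE) {
  assert_that(file.exists(path), "file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     png = "png", tif = "tiff", tiff = "tiff",
                     dcm = "dicom", dicom = "dicom",
                     stop_calc("cannot guess image format of ", path,
                               class = "calcgraph_format_error"))
  }
  img <- switch(format,
    png = {
      depth <- png_bit_depth(path)
      a <- png::readPNG(path)
      assert_that(length(dim(a)) == 2L,
                  "colour or multi-channel PNG rejected: expected grayscale",
                  class = "calcgraph_format_error")
      mammogram_image(round(a * (2^depth - 1)), source_id = basename(path),
                      bit_depth = depth)
    },
    tiff = {
      a <- tiff::readTIFF(path, all = TRUE, info = TRUE)
      assert_that(length(a) == 1L, "multi-frame TIFF rejected",
                  class = "calcgraph_format_error")
      a <- a[[1L]]
      assert_that(length(dim(a)) == 2L,
                  "colour or multi-channel TIFF rejected: expected grayscale",
                  class = "calcgraph_format_error")
      depth <- attr(a, "bits.per.sample") %||% 16L
      px <- matrix(round(a * (2^depth - 1)), nrow(a), ncol(a))
      mammogram_image(px, source_id = basename(path),
                      bit_depth = as.integer(depth))
    },
    dicom = read_dicom_image(path),
    stop_calc("unsupported format: ", format,
              class = "calcgraph_format_error"))
  if (normalize && !is.na(img$bit_depth)) {
    img$pixels <- img$pixels / (2^img$bit_depth - 1)
    img$bit_depth <- NA_integer_
  }
  img
}

#' Write a mammogram image to PNG or TIFF
#'
#' Integer-valued images round-trip bit-exactly through `write_image()` /
#' [read_image()]. PNG output is 8- or 16-bit according to `bit_depth`; TIFF
#' output uses 16 bits unless told otherwise.
#'
#' @param image A [mammogram_image()] or plain matrix.
#' @param path Output path; the extension selects the format.
#' @param bit_depth Target bit depth (default: the image's own, else 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = NULL) {
  if (is.matrix(image)) image <- mammogram_image(image)
  depth <- bit_depth %||% (if (is.na(image$bit_depth)) 16L else image$bit_depth)
  px <- image$pixels
  if (is.na(image$bit_depth)) {
    assert_that(max(px) <= 1, "unit-scaled image expected when bit_depth is NA")
    px <- round(px * (2^depth - 1))
  }
  assert_that(max(px) <= 2^depth - 1, "intensities exceed target bit depth")
  ext <- tolower(tools::file_ext(path))
  scaled <- px / (2^depth - 1)
  if (ext == "png") {
    assert_that(depth <= 8,
                "PNG output is 8-bit; use TIFF for deeper images",
                class = "calcgraph_format_error")
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(depth))
  } else {
    stop_calc("unsupported output format: ", ext,
              class = "calcgraph_format_error")
  }
  invisible(path)
}

#' Read region-of-interest annotations
#'
#' Annotations are a JSON list of
#' `{image_id, geometry: {type, params}, label}` where `type` is `"circle"`
#' (params `cx, cy, r`) or `"polygon"` (params `x`, `y` vertex vectors) and
#' `label` is one of the five distribution classes.
#'
#' @param path JSON file path.
#' @return A list of `roi_annotation` objects.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    lab <- as_calc_label(a$label)
    structure(list(image_id = a$image_id %||% "unknown",
                   geometry = lapply(a$geometry, function(g)
                     if (is.list(g)) unlist(g) else g),
                   label = lab),
              class = "roi_annotation")
  })
}

#' @rdname read_annotations
#' @param annotations List of `roi_annotation` objects.
#' @export
write_annotations <- function(annotations, path) {
  out <- lapply(annotations, function(a)
    list(image_id = a$image_id, geometry = a$geometry,
         label = as.character(a$label)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Segment the breast region
#'
#' Applies a global Otsu threshold to separate the bright breast from the dark
#' background, keeps the largest 8-connected foreground component, and fills
#' interior holes. An optional border margin is cleared first to suppress
#' film-edge artifacts.
#'
#' @param image A [mammogram_image()] or matrix.
#' @param border_margin Pixels to clear along each image border before
#'   component analysis (default 0).
#'
#' @return An object of class `breast_mask` with elements `mask` (logical
#'   matrix), `threshold`, and `area_fraction`.
#' @export
segment_breast <- function(image, border_margin = 0L) {
  if (is.matrix(image)) image <- mammogram_image(image)
  px <- image$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    stop_calc("constant image: Otsu threshold undefined",
              class = "calcgraph_degenerate_error")
  }
  levels <- if (!is.na(image$bit_depth)) 2^image$bit_depth else 256L
  scale <- if (!is.na(image$bit_depth)) 2^image$bit_depth - 1 else max(px)
  thr <- EBImage::otsu(px / scale, range = c(0, 1),
                       levels = min(levels, 65536L)) * scale
  fg <- px > thr
  if (border_margin > 0) {
    m <- border_margin
    fg[seq_len(m), ] <- FALSE
    fg[nrow(fg) - seq_len(m) + 1L, ] <- FALSE
    fg[, seq_len(m)] <- FALSE
    fg[, ncol(fg) - seq_len(m) + 1L] <- FALSE
  }
  assert_that(any(fg), "no foreground pixels above Otsu threshold",
              class = "calcgraph_degenerate_error")
  lab <- .cg_label_components(matrix(as.integer(fg), nrow(fg)), 8L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask))) > 0
  structure(list(mask = mask, threshold = thr,
                 area_fraction = mean(mask)),
            class = "breast_mask")
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask> %d x %d, area fraction %.3f, threshold %.4g\n",
              nrow(x$mask), ncol(x$mask), x$area_fraction, x$threshold))
  invisible(x)
}
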