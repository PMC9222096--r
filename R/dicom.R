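# Minimal DICOM (single-frame grayscale MG) reader, plus an internal writer
# used to build synthetic fixtures in tests. Supports the explicit- and
# implicit-VR little-endian transfer syntaxes and uncompressed 8/16-bit
# unsigned pixel data; everything else is rejected with a format error.

dcm_tag <- function(group, element) sprintf("%04x,%04x", group, element)

read_dicom_image <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132L)
  assert_that(length(preamble) == 132L &&
                rawToChar(preamble[129:132]) == "DICM",
              "not a DICOM file (missing DICM marker): ", path,
              class = "calcgraph_format_error")

  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  repeat {
    hdr <- readBin(con, "raw", n = 4L)
    if (length(hdr) < 4L) break
    group <- readBin(hdr[1:2], "integer", size = 2, signed = FALSE,
                     endian = "little")
    element <- readBin(hdr[3:4], "integer", size = 2, signed = FALSE,
                       endian = "little")
    vr_raw <- readBin(con, "raw", n = 2L)
    vr <- rawToChar(vr_raw)
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        readBin(con, "raw", n = 2L)  # reserved
        len <- readBin(con, "integer", size = 4, endian = "little")
      } else {
        len <- readBin(con, "integer", size = 2, signed = FALSE,
                       endian = "little")
      }
    } else {
      # implicit VR: those two bytes were the start of a 4-byte length
      rest <- readBin(con, "raw", n = 2L)
      len <- readBin(c(vr_raw, rest), "integer", size = 4, endian = "little")
      vr <- NA_character_
    }
    assert_that(len >= 0, "unsupported undefined-length DICOM element",
                class = "calcgraph_format_error")
    val <- readBin(con, "raw", n = len)
    elems[[dcm_tag(group, element)]] <- list(vr = vr, value = val)
    if (group == 0x7fe0 && element == 0x0010) break
  }

  get_us <- function(tag, default = NULL) {
    e <- elems[[tag]]
    if (is.null(e)) return(default)
    readBin(e$value, "integer", size = 2, signed = FALSE, endian = "little")
  }
  get_str <- function(tag, default = NULL) {
    e <- elems[[tag]]
    if (is.null(e)) return(default)
    trimws(rawToChar(e$value))
  }

  samples <- get_us(dcm_tag(0x0028, 0x0002), 1L)
  assert_that(samples == 1L, "colour DICOM rejected: SamplesPerPixel = ",
              samples, class = "calcgraph_format_error")
  n_frames <- suppressWarnings(as.integer(get_str(dcm_tag(0x0028, 0x0008), "1")))
  assert_that(is.na(n_frames) || n_frames <= 1L,
              "multi-frame DICOM rejected: NumberOfFrames = ", n_frames,
              class = "calcgraph_format_error")
  rows <- get_us(dcm_tag(0x0028, 0x0010))
  cols <- get_us(dcm_tag(0x0028, 0x0011))
  assert_that(!is.null(rows) && !is.null(cols), "DICOM missing Rows/Columns",
              class = "calcgraph_format_error")
  bits_alloc <- get_us(dcm_tag(0x0028, 0x0100), 16L)
  bits_stored <- get_us(dcm_tag(0x0028, 0x0101), bits_alloc)
  pixel_rep <- get_us(dcm_tag(0x0028, 0x0103), 0L)
  assert_that(pixel_rep == 0L, "signed DICOM pixel data unsupported",
              class = "calcgraph_format_error")
  photometric <- get_str(dcm_tag(0x0028, 0x0004), "MONOCHROME2")

  pd <- elems[[dcm_tag(0x7fe0, 0x0010)]]
  assert_that(!is.null(pd), "DICOM missing PixelData",
              class = "calcgraph_format_error")
  if (bits_alloc == 16L) {
    v <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                 signed = FALSE, endian = "little")
  } else if (bits_alloc == 8L) {
    v <- as.integer(pd$value[seq_len(rows * cols)])
  } else {
    stop_calc("unsupported BitsAllocated: ", bits_alloc,
              class = "calcgraph_format_error")
  }
  px <- matrix(as.numeric(v), nrow = rows, ncol = cols, byrow = TRUE)
  if (startsWith(photometric, "MONOCHROME1")) {
    px <- (2^bits_stored - 1) - px
  }
  spacing <- get_str(dcm_tag(0x0028, 0x0030))
  spacing <- if (!is.null(spacing))
    suppressWarnings(as.numeric(strsplit(spacing, "\\\\")[[1]][1])) else NULL
  mammogram_image(px, pixel_spacing = spacing,
                  view = get_str(dcm_tag(0x0018, 0x5101)),
                  laterality = get_str(dcm_tag(0x0020, 0x0062)),
                  source_id = basename(path),
                  bit_depth = as.integer(bits_stored))
}

# Internal fixture writer (explicit VR little endian, minimal tag set).
# Only intended for constructing synthetic test inputs.
write_minimal_dicom <- function(pixels, path, photometric = "MONOCHROME2",
                                bits_stored = 16L, view = NULL) {
  pixels <- round(pixels)
  assert_that(max(pixels) <= 2^bits_stored - 1 && min(pixels) >= 0,
              "pixel values exceed bits_stored")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)

  # pack unsigned 16-bit values as little-endian raw bytes (writeBin size = 2
  # cannot represent values above 32767)
  u16 <- function(x) {
    x <- as.integer(x)
    as.raw(rbind(x %% 256L, x %/% 256L))
  }
  short_el <- function(group, element, vr, value_raw) {
    if (length(value_raw) %% 2L == 1L)
      value_raw <- c(value_raw, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
    writeBin(u16(c(group, element)), con)
    writeBin(charToRaw(vr), con)
    writeBin(u16(length(value_raw)), con)
    writeBin(value_raw, con)
  }
  us <- u16

  short_el(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1"))
  short_el(0x0008, 0x0060, "CS", charToRaw("MG"))
  if (!is.null(view)) short_el(0x0018, 0x5101, "CS", charToRaw(view))
  short_el(0x0028, 0x0002, "US", us(1L))
  short_el(0x0028, 0x0004, "CS", charToRaw(photometric))
  short_el(0x0028, 0x0010, "US", us(nrow(pixels)))
  short_el(0x0028, 0x0011, "US", us(ncol(pixels)))
  short_el(0x0028, 0x0100, "US", us(16L))
  short_el(0x0028, 0x0101, "US", us(bits_stored))
  short_el(0x0028, 0x0102, "US", us(bits_stored - 1L))
  short_el(0x0028, 0x0103, "US", us(0L))

  # PixelData, OW with 4-byte length, row-major
  writeBin(u16(c(0x7fe0L, 0x0010L)), con)
  writeBin(charToRaw("OW"), con)
  writeBin(raw(2L), con)
  writeBin(as.integer(2L * length(pixels)), con, size = 4, endian = "little")
  writeBin(u16(as.integer(t(pixels))), con)
  invisible(path)
}
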