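# Raster input/output, blue-channel extraction and full-range rescaling.
#
# All images are held in memory as base-R numeric arrays of integers on the
# 16-bit scale: a slice_image is rows x cols x 3 (RGB order, row 1 at the
# top), a channel_image is a rows x cols matrix in [0, 65535].

#' Construct a slice image
#'
#' A `slice_image` is the unit of input: an RGB raster of integer
#' intensities with a per-channel bit depth. Pixel coordinates are
#' 1-based `(row, col)` with row 1 at the top of the picture.
#'
#' @param pixels numeric array `rows x cols x 3`, channels in RGB order,
#'   integer values in `[0, 2^bit_depth)`.
#' @param bit_depth bits per channel, 8 or 16.
#' @param source_path provenance string (file of origin or `"synthetic"`).
#' @return an object of class `slice_image`.
#' @export
slice_image <- function(pixels, bit_depth, source_path = "") {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    ebtbr_error(
      sprintf("expected 3 color channels, got %s",
              if (length(dim(pixels)) == 3) dim(pixels)[3] else 1),
      "ebtbr_format_error")
  if (!bit_depth %in% c(8L, 16L))
    ebtbr_error("bit_depth must be 8 or 16", "ebtbr_format_error")
  if (min(pixels) < 0 || max(pixels) >= 2^bit_depth)
    ebtbr_error("pixel intensities outside [0, 2^bit_depth)",
                "ebtbr_format_error")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 source_path = source_path),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d px, %d bits/channel, source: %s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$bit_depth,
              if (nzchar(x$source_path)) x$source_path else "<memory>"))
  invisible(x)
}

#' Construct a single-channel image
#'
#' @param pixels numeric matrix of intensities in `[0, 65535]`.
#' @param rescaled has [rescale_full_range()] been applied?
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, rescaled = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    ebtbr_error("channel pixels must be a numeric matrix",
                "ebtbr_format_error")
  structure(list(pixels = pixels, rescaled = isTRUE(rescaled)),
            class = "channel_image")
}

#' Load a brain-slice photograph
#'
#' Reads a PNG, TIFF or JPEG file into a [slice_image()]. Channels are
#' returned in RGB order and intensities as integers at the file's native
#' bit depth. An alpha channel, if present, is dropped with a warning;
#' grayscale or CMYK files are rejected. JPEG is accepted but warned
#' against, since lossy compression perturbs the median intensities the
#' pipeline relies on.
#'
#' @param path path to an image file.
#' @return a [slice_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    ebtbr_error(sprintf("image file not found: %s", path), "ebtbr_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    raw <- png::readPNG(path, info = TRUE)
    bits <- attr(raw, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path)
    meta <- tiff::readTIFF(path, payload = FALSE)
    bits <- meta$bits.per.sample[1]
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      ebtbr_error("the 'jpeg' package is required to read JPEG files",
                  "ebtbr_io_error")
    warning("JPEG input is lossy-compressed; medians may be perturbed. ",
            "Prefer PNG or TIFF.", call. = FALSE)
    raw <- jpeg::readJPEG(path)
    bits <- 8L
  } else {
    ebtbr_error(sprintf("unsupported image format: .%s", ext),
                "ebtbr_format_error")
  }
  d <- dim(raw)
  if (length(d) != 3 || d[3] < 3)
    ebtbr_error(
      sprintf("expected a 3-channel RGB image, got %d channel(s): %s",
              if (length(d) == 3) d[3] else 1L, path),
      "ebtbr_format_error")
  if (d[3] > 4)
    ebtbr_error(
      sprintf("expected a 3-channel RGB image, got %d channel(s): %s",
              d[3], path),
      "ebtbr_format_error")
  if (d[3] == 4) {
    warning("dropping alpha channel of ", path, call. = FALSE)
    raw <- raw[, , 1:3, drop = FALSE]
  }
  # readers return values normalized to [0, 1]; recover integer intensities
  pixels <- array(as.numeric(round(raw * (2^bits - 1))), dim(raw))
  slice_image(pixels, bit_depth = as.integer(bits), source_path = path)
}

#' Write an image to disk
#'
#' 16-bit output goes to TIFF; PNG output is 8-bit (used for binary masks
#' and overlays for visual audit).
#'
#' @param pixels a [slice_image()], a `rows x cols x 3` array, or a matrix
#'   of integer intensities.
#' @param path destination; extension selects the format (`.tif`/`.tiff`
#'   or `.png`).
#' @param bit_depth intensity scale of `pixels` (ignored for a
#'   `slice_image`, which carries its own).
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path, bit_depth = 16L) {
  if (inherits(pixels, "slice_image")) {
    bit_depth <- pixels$bit_depth
    pixels <- pixels$pixels
  }
  maxv <- 2^bit_depth - 1
  norm <- pmin(pmax(pixels / maxv, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = as.integer(bit_depth))
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    ebtbr_error(sprintf("unsupported output format: .%s", ext),
                "ebtbr_format_error")
  }
  invisible(path)
}

#' Extract the blue channel
#'
#' In the additive RGB model the blue channel tracks the amount of Evans
#' blue dye, so all downstream measurement happens on this plane. 8-bit
#' inputs are promoted to the 16-bit scale by multiplying by 257, so that
#' 255 maps exactly to 65535.
#'
#' @param img a [slice_image()].
#' @return a [channel_image()] with `rescaled = FALSE`.
#' @export
extract_blue_channel <- function(img) {
  stopifnot(inherits(img, "slice_image"))
  blue <- img$pixels[, , 3]
  if (img$bit_depth == 8L) blue <- blue * 257
  channel_image(blue, rescaled = FALSE)
}

#' Rescale a channel to the full 16-bit range
#'
#' Linearly maps the observed minimum to 0 and the observed maximum to
#' 65535 (the largest value representable in uint16), rounding to the
#' nearest integer. This removes between-image differences in illumination
#' offset and gain before intensities are compared. The map is idempotent
#' and invariant under positive affine transforms of the input.
#'
#' @param ch a [channel_image()].
#' @return the rescaled [channel_image()] with `rescaled = TRUE`.
#' @export
rescale_full_range <- function(ch) {
  stopifnot(inherits(ch, "channel_image"))
  mn <- min(ch$pixels)
  mx <- max(ch$pixels)
  if (mx == mn)
    ebtbr_error("constant image: full-range rescaling is undefined",
                "ebtbr_degenerate_error")
  out <- round((ch$pixels - mn) / (mx - mn) * UINT16_MAX)
  channel_image(out, rescaled = TRUE)
}
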