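# Brain/background segmentation: the binary mask that carries all spatial
# information used downstream. Three alternative filters are provided, as
# image quality dictates which works best on a given slice: a plain
# intensity threshold, a gradient-magnitude band with contour fill, and a
# Canny edge detector followed by contour interpolation.

#' Segmentation filter configuration
#'
#' Thresholds are expressed on the rescaled 16-bit intensity scale and are
#' per-image settings, chosen to match image quality (batch runs carry
#' them in the run config). `NULL` thresholds select automatic defaults:
#' Otsu's threshold for intensity mode, and magnitude-derived hysteresis
#' levels for Canny mode.
#'
#' @param mode one of `"intensity"`, `"gradient"`, `"canny"`.
#' @param intensity_threshold foreground cut in `[0, 65535]`; `NULL` for
#'   Otsu's automatic threshold.
#' @param gradient_threshold gradient-magnitude cut (intensity units per
#'   pixel), must be > 0 for gradient mode.
#' @param canny_sigma Gaussian smoothing scale in pixels.
#' @param canny_low,canny_high hysteresis thresholds on the suppressed
#'   gradient magnitude, `canny_low < canny_high`; `NULL` derives
#'   `canny_high` as half the maximum suppressed magnitude and
#'   `canny_low` as 0.4 `canny_high`.
#' @param min_object_area connected components smaller than this many
#'   pixels are discarded as specks.
#' @param closing_radius radius (pixels) of the disc used to interpolate
#'   (morphologically close) broken contours in Canny mode.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(mode = c("intensity", "gradient", "canny"),
                          intensity_threshold = NULL,
                          gradient_threshold = NULL,
                          canny_sigma = 2,
                          canny_low = NULL,
                          canny_high = NULL,
                          min_object_area = 64,
                          closing_radius = 5) {
  mode <- match.arg(mode)
  if (!is.null(intensity_threshold) &&
      (intensity_threshold < 0 || intensity_threshold > UINT16_MAX))
    ebtbr_error("intensity_threshold outside [0, 65535]",
                "ebtbr_parameter_error")
  if (!is.null(gradient_threshold) && gradient_threshold < 0)
    ebtbr_error("gradient_threshold must be >= 0", "ebtbr_parameter_error")
  if (!is.null(canny_low) && !is.null(canny_high) && canny_low >= canny_high)
    ebtbr_error("canny_low must be < canny_high", "ebtbr_parameter_error")
  if (canny_sigma <= 0)
    ebtbr_error("canny_sigma must be > 0", "ebtbr_parameter_error")
  structure(list(mode = mode,
                 intensity_threshold = intensity_threshold,
                 gradient_threshold = gradient_threshold,
                 canny_sigma = canny_sigma,
                 canny_low = canny_low,
                 canny_high = canny_high,
                 min_object_area = min_object_area,
                 closing_radius = closing_radius),
            class = "filter_config")
}

#' Construct a brain mask
#'
#' Binary matrix congruent with its channel: 1 where a pixel represents
#' brain, 0 where it represents background.
#'
#' @param pixels 0/1 numeric matrix (or logical).
#' @return an object of class `brain_mask` with the connected foreground
#'   component count in `n_components`.
#' @export
brain_mask <- function(pixels) {
  px <- (as_binary(pixels)) * 1
  if (sum(px) == 0)
    ebtbr_error("mask has no foreground pixels", "ebtbr_empty_mask_error")
  ncomp <- max(EBImage::bwlabel(px))
  structure(list(pixels = px, n_components = as.integer(ncomp)),
            class = "brain_mask")
}

ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Drop connected components smaller than min_area pixels.
remove_specks <- function(bin, min_area) {
  if (min_area <= 1 || sum(bin) == 0) return(bin)
  lab <- ebi_mat(EBImage::bwlabel(bin))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  matrix(as.numeric(lab %in% keep), nrow(bin), ncol(bin))
}

fill_holes <- function(bin) {
  (ebi_mat(EBImage::fillHull(bin)) > 0.5) * 1
}

largest_component <- function(bin) {
  lab <- ebi_mat(EBImage::bwlabel(bin))
  sizes <- tabulate(lab)
  if (length(sizes) == 0)
    ebtbr_error("mask has no foreground pixels", "ebtbr_empty_mask_error")
  (lab == which.max(sizes)) * 1
}

# Central-difference gradient with replicate padding at the borders.
gradient_xy <- function(x) {
  list(gx = (shift_mat(x, 0, 1) - shift_mat(x, 0, -1)) / 2,
       gy = (shift_mat(x, 1, 0) - shift_mat(x, -1, 0)) / 2)
}

# Separable Gaussian smoothing with replicate padding, kernel truncated
# at 3 sigma.
gaussian_smooth <- function(x, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- 0 * x
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(x, i - r - 1L, 0L)
  x <- out
  out <- 0 * x
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(x, 0L, i - r - 1L)
  out
}

#' Intensity-threshold segmentation
#'
#' Foreground is the set of pixels at or above `intensity_threshold`
#' (Otsu's threshold when `NULL`); specks below `min_object_area` are
#' removed and interior holes filled.
#'
#' @param ch a rescaled [channel_image()].
#' @param cfg a [filter_config()].
#' @return a [brain_mask()].
#' @export
intensity_filter <- function(ch, cfg = filter_config("intensity")) {
  stopifnot(inherits(ch, "channel_image"))
  thr <- cfg$intensity_threshold
  if (is.null(thr)) {
    thr <- EBImage::otsu(ch$pixels / UINT16_MAX, range = c(0, 1)) * UINT16_MAX
    ebtbr_log(sprintf("intensity_filter: Otsu threshold %.0f", thr))
  }
  bin <- (ch$pixels >= thr) * 1
  if (sum(bin) == 0)
    ebtbr_error(sprintf(
      "intensity threshold %.0f selects zero pixels", thr),
      "ebtbr_empty_mask_error")
  bin <- remove_specks(bin, cfg$min_object_area)
  if (sum(bin) == 0)
    ebtbr_error("all foreground removed as specks; lower min_object_area",
                "ebtbr_empty_mask_error")
  brain_mask(fill_holes(bin))
}

#' Gradient-band segmentation
#'
#' Thresholds the central-difference gradient magnitude to an edge band;
#' the region the band encloses is filled to produce the mask. Because the
#' central difference responds one pixel on either side of an edge, the
#' filled region is eroded by one pixel to re-centre the boundary on the
#' true edge. Fails with an open-contour error when the band encloses
#' nothing (e.g. a flat image), in which case Canny mode with contour
#' interpolation is the remedy.
#'
#' @inheritParams intensity_filter
#' @return a [brain_mask()].
#' @export
gradient_filter <- function(ch, cfg = filter_config("gradient")) {
  stopifnot(inherits(ch, "channel_image"))
  if (is.null(cfg$gradient_threshold))
    ebtbr_error("gradient mode requires gradient_threshold",
                "ebtbr_parameter_error")
  g <- gradient_xy(ch$pixels)
  mag <- sqrt(g$gx^2 + g$gy^2)
  band <- (mag >= cfg$gradient_threshold) * 1
  filled <- fill_holes(band)
  if (sum(filled) == sum(band))
    ebtbr_error(paste0(
      "gradient band does not enclose any region (open contour); ",
      "consider canny mode, which interpolates broken contours"),
      "ebtbr_open_contour_error")
  eroded <- (ebi_mat(EBImage::erode(filled,
                                    EBImage::makeBrush(3, "diamond"))) > 0.5) * 1
  eroded <- remove_specks(eroded, cfg$min_object_area)
  if (sum(eroded) == 0)
    ebtbr_error("gradient mask empty after speck removal",
                "ebtbr_empty_mask_error")
  brain_mask(fill_holes(eroded))
}

# Canny edge map: Gaussian smoothing, central-difference gradient,
# non-maximum suppression along the quantized gradient direction, and
# hysteresis keeping weak edges connected to strong ones.
canny_edges <- function(x, sigma, low = NULL, high = NULL) {
  xs <- gaussian_smooth(x, sigma)
  g <- gradient_xy(xs)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # quantize direction (mod 180 degrees) into 4 sectors
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4))
  n1 <- shift_mat(mag, 0, 1);  n2 <- shift_mat(mag, 0, -1)
  m_se <- shift_mat(mag, 1, 1);  m_nw <- shift_mat(mag, -1, -1)
  m_s  <- shift_mat(mag, 1, 0);  m_n  <- shift_mat(mag, -1, 0)
  m_sw <- shift_mat(mag, 1, -1); m_ne <- shift_mat(mag, -1, 1)
  i <- sector == 1; n1[i] <- m_se[i]; n2[i] <- m_nw[i]
  i <- sector == 2; n1[i] <- m_s[i];  n2[i] <- m_n[i]
  i <- sector == 3; n1[i] <- m_sw[i]; n2[i] <- m_ne[i]
  nms <- ifelse(mag >= n1 & mag >= n2, mag, 0)
  if (is.null(high)) high <- 0.5 * max(nms)
  if (is.null(low)) low <- 0.4 * high
  strong <- nms >= high
  weak <- (nms >= low) * 1
  if (!any(strong)) return(matrix(0, nrow(x), ncol(x)))
  # hysteresis: keep weak-edge chains that contain a strong pixel; the
  # one-pixel dilation before labelling joins 8-connected chains
  lab <- ebi_mat(EBImage::bwlabel(
    (ebi_mat(EBImage::dilate(weak, EBImage::makeBrush(3, "box"))) > 0.5) * 1))
  keep <- unique(lab[strong & lab > 0])
  matrix(as.numeric(lab %in% keep & weak > 0), nrow(x), ncol(x))
}

#' Canny segmentation with contour interpolation
#'
#' Runs the Canny edge detector (Gaussian smoothing at `canny_sigma`,
#' gradient magnitude and direction, non-maximum suppression, hysteresis
#' with `canny_low`/`canny_high`), then interpolates broken contours by
#' morphological closing with a disc of `closing_radius` pixels, fills the
#' enclosed region, and keeps the largest connected component — one brain
#' per slice.
#'
#' @inheritParams intensity_filter
#' @return a [brain_mask()] with a single connected component.
#' @export
canny_mask <- function(ch, cfg = filter_config("canny")) {
  stopifnot(inherits(ch, "channel_image"))
  edges <- canny_edges(ch$pixels, cfg$canny_sigma, cfg$canny_low,
                       cfg$canny_high)
  if (sum(edges) == 0)
    ebtbr_error("no edges detected", "ebtbr_open_contour_error")
  brush <- EBImage::makeBrush(2L * as.integer(cfg$closing_radius) + 1L, "disc")
  closed <- (ebi_mat(EBImage::closing(edges, brush)) > 0.5) * 1
  filled <- fill_holes(closed)
  if (sum(filled) == sum(closed))
    ebtbr_error(paste0(
      "canny contour does not enclose any region even after contour ",
      "interpolation; increase closing_radius or adjust thresholds"),
      "ebtbr_open_contour_error")
  filled <- remove_specks(filled, cfg$min_object_area)
  if (sum(filled) == 0)
    ebtbr_error("canny mask empty after speck removal",
                "ebtbr_empty_mask_error")
  brain_mask(largest_component(filled))
}

#' Segment brain from background
#'
#' Dispatches to the filter selected by `cfg$mode` and logs the mask area
#' fraction (under `options(ebtbr.verbose = TRUE)`).
#'
#' @inheritParams intensity_filter
#' @return a [brain_mask()].
#' @export
segment_brain <- function(ch, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  mask <- tryCatch(
    switch(cfg$mode,
           intensity = intensity_filter(ch, cfg),
           gradient = gradient_filter(ch, cfg),
           canny = canny_mask(ch, cfg)),
    ebtbr_error = function(e) {
      ebtbr_error(sprintf("[mode=%s] %s", cfg$mode, conditionMessage(e)),
                  class(e)[1])
    })
  ebtbr_log(sprintf("segment_brain[%s]: area fraction %.3f, %d component(s)",
                    cfg$mode, mean(mask$pixels), mask$n_components))
  mask
}

#' Apply a binary mask to a channel
#'
#' Element-wise product: background pixels become 0 while brain pixels are
#' kept, so the mask's spatial information is imposed by plain matrix
#' multiplication.
#'
#' @param ch a [channel_image()].
#' @param mask a [brain_mask()] congruent with `ch`.
#' @return a [channel_image()] with background zeroed.
#' @export
apply_mask <- function(ch, mask) {
  stopifnot(inherits(ch, "channel_image"), inherits(mask, "brain_mask"))
  if (!identical(dim(ch$pixels), dim(mask$pixels)))
    ebtbr_error("channel and mask dimensions differ",
                "ebtbr_congruence_error")
  channel_image(ch$pixels * mask$pixels, rescaled = ch$rescaled)
}
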