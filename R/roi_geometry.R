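# Cutout geometry: crop to the mask bounding box, define the upper region
# of interest, and place the four measurement squares.
#
# Coordinates are 1-based (row, col) with row 1 at the top; a square with
# top-left corner (r, c) and side s occupies rows r..r+s-1 and columns
# c..c+s-1.

#' Crop a channel to its mask bounding box
#'
#' Crops channel and mask down to the outermost brain pixel: the tight
#' bounding box of the mask foreground. The crop origin in the full image
#' is retained in `offset` so cutout coordinates can be mapped back.
#'
#' @param ch a [channel_image()].
#' @param mask a congruent [brain_mask()].
#' @return an object of class `cutout_image` with fields `pixels`, `mask`
#'   and `offset` (1-based (row, col) of the cutout origin).
#' @export
crop_to_mask <- function(ch, mask) {
  stopifnot(inherits(ch, "channel_image"), inherits(mask, "brain_mask"))
  if (!identical(dim(ch$pixels), dim(mask$pixels)))
    ebtbr_error("channel and mask dimensions differ",
                "ebtbr_congruence_error")
  fg <- which(mask$pixels > 0, arr.ind = TRUE)
  if (nrow(fg) == 0)
    ebtbr_error("cannot crop to an empty mask", "ebtbr_empty_mask_error")
  r1 <- min(fg[, 1]); r2 <- max(fg[, 1])
  c1 <- min(fg[, 2]); c2 <- max(fg[, 2])
  structure(list(pixels = ch$pixels[r1:r2, c1:c2, drop = FALSE],
                 mask = mask$pixels[r1:r2, c1:c2, drop = FALSE],
                 offset = c(row = r1, col = c1),
                 rescaled = ch$rescaled),
            class = "cutout_image")
}

#' Define the upper region of interest
#'
#' The upper fraction (default 20%) of the cutout approximates the cortex
#' between the upper cortical surface and the ventricles — the band in
#' which the cranial-window (target) and contralateral (background)
#' squares are placed.
#'
#' @param cut a [crop_to_mask()] cutout.
#' @param fraction fraction of cutout rows in the band, in (0, 1\].
#' @return an object of class `roi_band` with `n_rows`
#'   (`ceiling(fraction * rows)`: the band covers rows `1..n_rows`) and
#'   `fraction`.
#' @export
define_roi <- function(cut, fraction = 0.20) {
  stopifnot(inherits(cut, "cutout_image"))
  if (!(fraction > 0 && fraction <= 1))
    ebtbr_error("roi fraction must be in (0, 1]", "ebtbr_parameter_error")
  structure(list(n_rows = as.integer(ceiling(fraction * nrow(cut$pixels))),
                 fraction = fraction),
            class = "roi_band")
}

square_in_bounds <- function(corner, side, dims) {
  corner[1] >= 1 && corner[2] >= 1 &&
    corner[1] + side - 1 <= dims[1] && corner[2] + side - 1 <= dims[2]
}

#' Place the four measurement squares
#'
#' The target square is centred on the user-supplied seed (the centre of
#' the cranial-window area), clamped inward if the centred extent would
#' leave the cutout. The background square is its horizontal mirror image
#' about the cutout's vertical midline — the homologous position in the
#' contralateral hemisphere. Two equally sized normalization squares sit
#' in the bottom band of the image, clearly outside the ROI, one under
#' each upper square (shared columns). The target position is also stored
#' as distances from the mask bounding-box edges (`seed_distances`), which
#' is sufficient to re-place all four squares reproducibly.
#'
#' @param cut a [crop_to_mask()] cutout.
#' @param seed `(row, col)` seed point in cutout coordinates.
#' @param roi a [define_roi()] band; the target square must intersect it.
#' @param side square side in pixels (default 50, about 0.3 mm^2 at the
#'   source magnification).
#' @param margin gap in pixels between the normalization squares and the
#'   bottom cutout edge.
#' @return an object of class `square_placement` with `(row, col)`
#'   top-left corners `target`, `background`, `norm_ipsi`, `norm_contra`,
#'   plus `side`, `seed_distances` (top, bottom, left, right pixel
#'   distances from the target square to the cutout edges) and
#'   `fg_fraction` (mask-foreground fraction inside each square).
#' @export
place_squares <- function(cut, seed, roi = define_roi(cut), side = 50,
                          margin = 5) {
  stopifnot(inherits(cut, "cutout_image"), inherits(roi, "roi_band"))
  dims <- dim(cut$pixels)
  seed <- as.integer(round(seed))
  if (seed[1] < 1 || seed[1] > dims[1] || seed[2] < 1 || seed[2] > dims[2])
    ebtbr_error(sprintf("seed (%d, %d) lies outside the cutout (%d x %d)",
                        seed[1], seed[2], dims[1], dims[2]),
                "ebtbr_placement_error")
  if (side < 1 || side > min(dims))
    ebtbr_error("square side exceeds cutout extent",
                "ebtbr_placement_error")
  half <- as.integer(floor(side / 2))
  t_row <- seed[1] - half
  t_col <- seed[2] - half
  clamped_row <- min(max(t_row, 1L), dims[1] - side + 1L)
  clamped_col <- min(max(t_col, 1L), dims[2] - side + 1L)
  if (clamped_row != t_row || clamped_col != t_col)
    warning("target square shifted inward to fit the cutout", call. = FALSE)
  t_row <- clamped_row; t_col <- clamped_col
  if (t_row > roi$n_rows)
    ebtbr_error(sprintf(
      "target square (rows %d..%d) does not intersect the ROI (rows 1..%d)",
      t_row, t_row + side - 1L, roi$n_rows), "ebtbr_placement_error")
  # horizontal mirror about the vertical midline, same rows
  b_col <- dims[2] - t_col - side + 2L
  if (b_col == t_col)
    warning("seed on the vertical midline: target and background coincide",
            call. = FALSE)
  n_row <- dims[1] - side - as.integer(margin) + 1L
  squares <- list(target = c(t_row, t_col),
                  background = c(t_row, b_col),
                  norm_ipsi = c(n_row, t_col),
                  norm_contra = c(n_row, b_col))
  for (nm in names(squares)) {
    if (!square_in_bounds(squares[[nm]], side, dims))
      ebtbr_error(sprintf("square '%s' falls outside the cutout", nm),
                  "ebtbr_placement_error")
  }
  fg <- vapply(squares, function(cr) {
    mean(cut$mask[cr[1]:(cr[1] + side - 1), cr[2]:(cr[2] + side - 1)])
  }, numeric(1))
  ebtbr_log(sprintf("place_squares: foreground fractions %s",
                    paste(sprintf("%s=%.2f", names(fg), fg), collapse = " ")))
  structure(c(squares,
              list(side = as.integer(side),
                   margin = as.integer(margin),
                   seed_distances = c(top = t_row - 1L,
                                      bottom = dims[1] - (t_row - 1L) - side,
                                      left = t_col - 1L,
                                      right = dims[2] - (t_col - 1L) - side),
                   fg_fraction = fg)),
            class = "square_placement")
}

#' Re-place squares from stored seed distances
#'
#' Reconstructs a [place_squares()] placement on a (possibly re-derived)
#' cutout from the stored distances between the target square and the mask
#' bounding-box edges, making placements replayable without the original
#' interactive seed.
#'
#' @param cut a [crop_to_mask()] cutout.
#' @param seed_distances named vector `(top, bottom, left, right)` as
#'   stored in a `square_placement`.
#' @param roi a [define_roi()] band.
#' @param side,margin as in [place_squares()].
#' @return a `square_placement`.
#' @export
squares_from_distances <- function(cut, seed_distances, roi = define_roi(cut),
                                   side = 50, margin = 5) {
  half <- as.integer(floor(side / 2))
  seed <- c(seed_distances[["top"]] + 1L + half,
            seed_distances[["left"]] + 1L + half)
  place_squares(cut, seed, roi, side = side, margin = margin)
}

draw_rect <- function(px, corner, side, value) {
  r <- corner[1]:(corner[1] + side - 1)
  c <- corner[2]:(corner[2] + side - 1)
  px[r[1], c] <- value; px[r[length(r)], c] <- value
  px[r, c[1]] <- value; px[r, c[length(c)]] <- value
  px
}

#' Render a visual-control overlay
#'
#' RGB copy of the cutout with the four squares outlined — the target in
#' blue, the background and both normalization squares in white — as a
#' visual control of the placement. Only the 1-pixel outlines are drawn;
#' pixels inside the squares are untouched.
#'
#' @param cut a [crop_to_mask()] cutout.
#' @param sq a [place_squares()] placement.
#' @return a [slice_image()] (16-bit) ready for [write_image()].
#' @export
render_overlay <- function(cut, sq) {
  stopifnot(inherits(cut, "cutout_image"), inherits(sq, "square_placement"))
  base <- cut$pixels
  rgb <- array(rep(base, 3), c(dim(base), 3))
  white <- list(UINT16_MAX, UINT16_MAX, UINT16_MAX)
  blue <- list(0, 0, UINT16_MAX)
  styles <- list(target = blue, background = white,
                 norm_ipsi = white, norm_contra = white)
  for (nm in names(styles)) {
    for (k in 1:3)
      rgb[, , k] <- draw_rect(rgb[, , k], sq[[nm]], sq$side, styles[[nm]][[k]])
  }
  slice_image(rgb, bit_depth = 16L, source_path = "overlay")
}
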