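# The target-to-background ratio (TBR): the pipeline's summary statistic.
#
# TBR = (median(target) / median(norm_ipsi)) /
#       (median(background) / median(norm_contra))
#
# Each upper square's median blue intensity is normalized by the bottom
# (remote) square of its own hemisphere; the ratio of the two relative
# values compares the cranial-window cortex to the homologous
# contralateral cortex. TBR > 1 indicates ipsilateral Evans blue excess.

#' Median intensity of a measurement square
#'
#' Median of the `side^2` pixel intensities at `corner`. Pixels the mask
#' marks as background are excluded (their zeroed values would drag the
#' median toward 0); the number excluded is attached as attribute
#' `n_excluded`. The median of an even count is the mean of the two
#' central order statistics.
#'
#' @param cut a [crop_to_mask()] cutout.
#' @param corner `(row, col)` top-left corner of the square.
#' @param side square side in pixels.
#' @param exclude_masked drop pixels with mask value 0?
#' @return the median intensity (numeric scalar).
#' @export
square_median <- function(cut, corner, side, exclude_masked = TRUE) {
  stopifnot(inherits(cut, "cutout_image"))
  if (!square_in_bounds(corner, side, dim(cut$pixels)))
    ebtbr_error(sprintf("square at (%d, %d) side %d is out of bounds",
                        corner[1], corner[2], side),
                "ebtbr_placement_error")
  rows <- corner[1]:(corner[1] + side - 1)
  cols <- corner[2]:(corner[2] + side - 1)
  vals <- cut$pixels[rows, cols]
  n_excluded <- 0L
  if (exclude_masked) {
    keep <- cut$mask[rows, cols] > 0
    n_excluded <- sum(!keep)
    if (n_excluded == length(vals))
      ebtbr_error("square contains no brain (mask-foreground) pixels",
                  "ebtbr_placement_error")
    vals <- vals[keep]
    if (n_excluded > 0)
      ebtbr_log(sprintf("square_median: excluded %d background pixel(s)",
                        n_excluded))
  }
  structure(stats::median(vals), n_excluded = n_excluded)
}

#' Compute the target-to-background ratio
#'
#' Populates a `tbr_result` from the four square medians. With
#' `single_normalizer = TRUE` both upper squares are normalized by the
#' ipsilateral bottom square only (one remote reference area) instead of
#' the default per-hemisphere normalizers.
#'
#' @param cut a [crop_to_mask()] cutout.
#' @param sq a [place_squares()] placement.
#' @param animal_id,group_label provenance strings carried into the result.
#' @param single_normalizer normalize both sides by the ipsilateral bottom
#'   square?
#' @return an object of class `tbr_result`: the four medians, the two
#'   relative side values `rel_ipsi`, `rel_contra`, and `tbr`.
#' @export
compute_tbr <- function(cut, sq, animal_id = "", group_label = "",
                        single_normalizer = FALSE) {
  stopifnot(inherits(sq, "square_placement"))
  med <- lapply(
    list(target = sq$target, background = sq$background,
         norm_ipsi = sq$norm_ipsi, norm_contra = sq$norm_contra),
    function(cr) as.numeric(square_median(cut, cr, sq$side)))
  bad <- names(med)[vapply(med, function(v) !is.finite(v) || v <= 0,
                           logical(1))]
  if (length(bad))
    ebtbr_error(sprintf(
      "median of square '%s' is zero or undefined; TBR needs positive medians",
      bad[1]), "ebtbr_degenerate_error")
  norm_contra_used <- if (single_normalizer) med$norm_ipsi else med$norm_contra
  rel_ipsi <- med$target / med$norm_ipsi
  rel_contra <- med$background / norm_contra_used
  structure(list(median_target = med$target,
                 median_background = med$background,
                 median_norm_ipsi = med$norm_ipsi,
                 median_norm_contra = med$norm_contra,
                 rel_ipsi = rel_ipsi,
                 rel_contra = rel_contra,
                 tbr = rel_ipsi / rel_contra,
                 single_normalizer = isTRUE(single_normalizer),
                 animal_id = animal_id,
                 group_label = group_label),
            class = "tbr_result")
}

#' @export
print.tbr_result <- function(x, ...) {
  cat(sprintf(
    "<tbr_result> %s%s TBR = %.4f (rel ipsi %.4f / rel contra %.4f)\n",
    if (nzchar(x$animal_id)) paste0(x$animal_id, " ") else "",
    if (nzchar(x$group_label)) paste0("[", x$group_label, "]") else "",
    x$tbr, x$rel_ipsi, x$rel_contra))
  invisible(x)
}

#' @export
as.data.frame.tbr_result <- function(x, ...) {
  data.frame(animal_id = x$animal_id, group = x$group_label,
             median_target = x$median_target,
             median_background = x$median_background,
             median_norm_ipsi = x$median_norm_ipsi,
             median_norm_contra = x$median_norm_contra,
             rel_ipsi = x$rel_ipsi, rel_contra = x$rel_contra,
             tbr = x$tbr, stringsAsFactors = FALSE)
}

#' Run the full pipeline on one image
#'
#' Convenience wrapper chaining blue-channel extraction, full-range
#' rescaling, segmentation, cropping, ROI definition, square placement and
#' the TBR computation for a single slice.
#'
#' @param img a [slice_image()], or a path passed to [load_image()].
#' @param seed `(row, col)` seed point for the target square, in
#'   full-image coordinates (converted to the cutout via its offset).
#' @param cfg a [filter_config()].
#' @param roi_fraction upper ROI fraction (default 0.20).
#' @param side,margin square geometry, see [place_squares()].
#' @param single_normalizer see [compute_tbr()].
#' @param rescale apply [rescale_full_range()]? (default TRUE)
#' @param animal_id,group_label provenance strings.
#' @return a list with `result` (a `tbr_result`), `placement`, `mask`,
#'   `cutout` and `roi`.
#' @export
assess_image <- function(img, seed, cfg = filter_config(),
                         roi_fraction = 0.20, side = 50, margin = 5,
                         single_normalizer = FALSE, rescale = TRUE,
                         animal_id = "", group_label = "") {
  if (is.character(img)) img <- load_image(img)
  ch <- extract_blue_channel(img)
  if (rescale) ch <- rescale_full_range(ch)
  mask <- segment_brain(ch, cfg)
  cut <- crop_to_mask(ch, mask)
  roi <- define_roi(cut, roi_fraction)
  seed_cut <- c(seed[1] - cut$offset[["row"]] + 1L,
                seed[2] - cut$offset[["col"]] + 1L)
  sq <- place_squares(cut, seed_cut, roi, side = side, margin = margin)
  res <- compute_tbr(cut, sq, animal_id = animal_id,
                     group_label = group_label,
                     single_normalizer = single_normalizer)
  list(result = res, placement = sq, mask = mask, cutout = cut, roi = roi)
}

#' Batch TBR over a list of runs
#'
#' Each run is a list with an image (`path` or `image`), a `seed`
#' `(row, col)` in full-image coordinates, and optional `id`, `group` and
#' `filter` (a [filter_config()]) entries. Failures are recorded per row
#' in the `error` column without aborting the batch, and output order
#' follows input order.
#'
#' @param runs list of run descriptors.
#' @param cfg default [filter_config()] for runs without their own.
#' @param ... further arguments passed to [assess_image()].
#' @return a data.frame with one row per run: id, group, the four medians,
#'   `rel_ipsi`, `rel_contra`, `tbr`, and `error` (`NA` on success).
#' @export
batch_tbr <- function(runs, cfg = filter_config(), ...) {
  if (length(runs) < 1)
    ebtbr_error("batch_tbr needs at least one run", "ebtbr_parameter_error")
  rows <- lapply(seq_along(runs), function(i) {
    run <- runs[[i]]
    id <- run$id %||% as.character(i)
    group <- run$group %||% ""
    out <- tryCatch({
      img <- run$image %||% run$path
      a <- assess_image(img, run$seed, cfg = run$filter %||% cfg,
                        animal_id = id, group_label = group, ...)
      cbind(as.data.frame(a$result), error = NA_character_,
            stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(animal_id = id, group = group,
                 median_target = NA_real_, median_background = NA_real_,
                 median_norm_ipsi = NA_real_, median_norm_contra = NA_real_,
                 rel_ipsi = NA_real_, rel_contra = NA_real_, tbr = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out
  })
  res <- do.call(rbind, rows)
  if (all(!is.na(res$error)))
    ebtbr_error("no run in the batch succeeded", "ebtbr_batch_error")
  res
}
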