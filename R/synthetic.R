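# Synthetic phantoms: brain-slice-like images with known ground truth, so
# every pipeline stage can be validated without animal data. A phantom is
# a bright ellipse ("brain", left-right symmetric about its vertical
# midline) on a dark background, optionally with a brighter blue disc
# ("leak") in the upper part of one hemisphere emulating focal Evans blue
# extravasation under a cranial window, plus a global affine illumination
# perturbation and additive Gaussian sensor noise.

#' Phantom parameters
#'
#' Defaults mirror the acquisition geometry of the source assay: 1040 x
#' 1392 px frames, a brain ellipse spanning most of the frame, a leak disc
#' centred in the upper part of the right hemisphere (inside the upper-20%
#' ROI after cropping), and additive noise at 2% of the 16-bit dynamic
#' range. The background is near-black (the slices are photographed
#' against a dark field), so blue intensity is proportional to signal and
#' the constructed `leak_ratio` is directly the ratio the pipeline should
#' recover.
#'
#' @param rows,cols image size in pixels.
#' @param brain_axes `(semi-height, semi-width)` of the brain ellipse in
#'   pixels; default `(0.35 * rows, 0.40 * cols)`.
#' @param background_level,tissue_level base blue intensities in
#'   `[0, 65535]`; `tissue_level` must exceed `background_level`.
#' @param leak_ratio multiplier (>= 1) applied to the blue intensity
#'   inside the leak disc.
#' @param leak_center `(row, col)` of the leak disc in full-image
#'   coordinates; default upper right hemisphere, inside the ROI band.
#' @param leak_radius leak disc radius in pixels; default
#'   `0.16 * brain_axes[1]`.
#' @param noise_sd additive Gaussian noise sd in intensity units; default
#'   2% of the dynamic range.
#' @param illumination_gain,illumination_offset global affine perturbation
#'   `x -> gain * x + offset` applied before noise.
#' @param seed RNG seed making the phantom reproducible.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(rows = 1040, cols = 1392,
                           brain_axes = c(0.35 * rows, 0.40 * cols),
                           background_level = 0,
                           tissue_level = 30000,
                           leak_ratio = 1,
                           leak_center = NULL,
                           leak_radius = 0.16 * brain_axes[1],
                           noise_sd = 0.02 * UINT16_MAX,
                           illumination_gain = 1,
                           illumination_offset = 0,
                           seed = 1L) {
  center <- c(rows / 2, cols / 2)
  if (is.null(leak_center))
    leak_center <- c(center[1] - 0.65 * brain_axes[1],
                     center[2] + 0.40 * brain_axes[2])
  p <- structure(list(rows = as.integer(rows), cols = as.integer(cols),
                      brain_axes = brain_axes, center = center,
                      background_level = background_level,
                      tissue_level = tissue_level,
                      leak_ratio = leak_ratio,
                      leak_center = leak_center,
                      leak_radius = leak_radius,
                      noise_sd = noise_sd,
                      illumination_gain = illumination_gain,
                      illumination_offset = illumination_offset,
                      seed = as.integer(seed)),
                 class = "phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$tissue_level <= p$background_level)
    ebtbr_error("tissue_level must exceed background_level",
                "ebtbr_parameter_error")
  if (p$leak_ratio < 1)
    ebtbr_error("leak_ratio must be >= 1", "ebtbr_parameter_error")
  if (p$tissue_level * p$leak_ratio * p$illumination_gain +
      p$illumination_offset > UINT16_MAX)
    ebtbr_error("leak intensity exceeds the 16-bit range",
                "ebtbr_parameter_error")
  # the leak disc must lie inside the upper half of the ellipse
  a <- p$brain_axes[1]; b <- p$brain_axes[2]
  u <- (p$leak_center[1] - p$center[1]) / a
  v <- (p$leak_center[2] - p$center[2]) / b
  reach <- sqrt(u^2 + v^2) + p$leak_radius / min(a, b)
  if (reach > 1)
    ebtbr_error("leak disc extends outside the brain ellipse",
                "ebtbr_parameter_error")
  if (p$leak_center[1] + p$leak_radius >= p$center[1])
    ebtbr_error("leak disc must lie in the upper half of the ellipse",
                "ebtbr_parameter_error")
  invisible(p)
}

#' Generate a phantom slice image with ground truth
#'
#' The blue plane takes `tissue_level` inside the brain ellipse
#' (`tissue_level * leak_ratio` inside the leak disc) and
#' `background_level` outside; red and green are attenuated copies of the
#' noiseless blue signal. The global affine illumination perturbation and
#' per-channel Gaussian noise are then applied and intensities clipped to
#' `[0, 65535]` and rounded. Identical `p$seed` gives a bit-identical
#' image.
#'
#' @param p a [phantom_params()].
#' @return a list with `image` (a [slice_image()], 16-bit) and `truth`
#'   (class `phantom_truth`: the analytic `mask` and `leak_region`,
#'   `true_ratio`, the `seed_point` — the leak centre, the natural seed
#'   for [assess_image()] — and the generating `params`).
#' @export
generate_phantom <- function(p = phantom_params()) {
  stopifnot(inherits(p, "phantom_params"))
  validate_phantom_params(p)
  r <- matrix(seq_len(p$rows), p$rows, p$cols)
  c <- matrix(seq_len(p$cols), p$rows, p$cols, byrow = TRUE)
  ellipse <- (((r - p$center[1]) / p$brain_axes[1])^2 +
                ((c - p$center[2]) / p$brain_axes[2])^2) <= 1
  leak <- ((r - p$leak_center[1])^2 + (c - p$leak_center[2])^2) <=
    p$leak_radius^2
  blue <- matrix(p$background_level, p$rows, p$cols)
  blue[ellipse] <- p$tissue_level
  blue[leak] <- p$tissue_level * p$leak_ratio
  channels <- list(red = 0.55 * blue, green = 0.40 * blue, blue = blue)
  pixels <- with_seed(p$seed, function() {
    vapply(channels, function(sig) {
      x <- sig * p$illumination_gain + p$illumination_offset
      if (p$noise_sd > 0)
        x <- x + rnorm(length(x), sd = p$noise_sd)
      round(pmin(pmax(x, 0), UINT16_MAX))
    }, numeric(p$rows * p$cols))
  })
  dim(pixels) <- c(p$rows, p$cols, 3)
  truth <- structure(list(mask = ellipse * 1, leak_region = leak * 1,
                          true_ratio = p$leak_ratio,
                          seed_point = round(p$leak_center),
                          params = p),
                     class = "phantom_truth")
  list(image = slice_image(pixels, bit_depth = 16L,
                           source_path = "synthetic"),
       truth = truth)
}

#' Generate a multi-group phantom cohort
#'
#' Emulates a four-arm animal study: `n` phantoms per group at the group's
#' leak ratio, with small per-animal jitter of geometry, staining level
#' and illumination so no two animals are identical. Deterministic given
#' `seed`.
#'
#' @param group_specs data.frame (or list of lists) with columns `label`,
#'   `n`, `leak_ratio`. The default reproduces the reference design:
#'   a positive-control arm with strong leakage (n = 8) against
#'   sham (n = 6), ET-1 (n = 7) and remote-SD (n = 5) arms without.
#' @param shared a [phantom_params()] supplying everything the specs do
#'   not vary.
#' @param seed master RNG seed.
#' @param jitter relative sd-free half-width of the uniform per-animal
#'   perturbation of axes, tissue level and gain (default 3%).
#' @return a list of entries `list(image, truth, label, id)`, groups in
#'   spec order.
#' @export
generate_cohort <- function(group_specs = default_group_specs(),
                            shared = phantom_params(), seed = 1L,
                            jitter = 0.03) {
  if (is.data.frame(group_specs))
    group_specs <- lapply(seq_len(nrow(group_specs)),
                          function(i) as.list(group_specs[i, ]))
  if (any(vapply(group_specs, function(g) g$n < 1, logical(1))))
    ebtbr_error("each group needs n >= 1", "ebtbr_parameter_error")
  n_total <- sum(vapply(group_specs, function(g) g$n, numeric(1)))
  draws <- with_seed(seed, function() {
    list(seeds = sample.int(2^31 - 2, n_total),
         ax = 1 + runif(n_total, -jitter, jitter),
         lev = 1 + runif(n_total, -jitter, jitter),
         gain = 1 + runif(n_total, -jitter, jitter),
         off = if (jitter > 0) runif(n_total, 0, 0.3 * shared$noise_sd)
               else numeric(n_total),
         dc_r = runif(n_total, -1, 1) * (jitter / 3) * shared$rows,
         dc_c = runif(n_total, -1, 1) * (jitter / 3) * shared$cols)
  })
  out <- vector("list", n_total)
  k <- 0L
  for (g in group_specs) {
    for (j in seq_len(g$n)) {
      k <- k + 1L
      p <- phantom_params(
        rows = shared$rows, cols = shared$cols,
        brain_axes = shared$brain_axes * draws$ax[k],
        background_level = shared$background_level,
        tissue_level = shared$tissue_level * draws$lev[k],
        leak_ratio = g$leak_ratio,
        leak_center = c(shared$center[1] - 0.65 * shared$brain_axes[1] *
                          draws$ax[k] + draws$dc_r[k],
                        shared$center[2] + 0.40 * shared$brain_axes[2] *
                          draws$ax[k] + draws$dc_c[k]),
        leak_radius = shared$leak_radius * draws$ax[k],
        noise_sd = shared$noise_sd,
        illumination_gain = shared$illumination_gain * draws$gain[k],
        illumination_offset = shared$illumination_offset + draws$off[k],
        seed = draws$seeds[k])
      ph <- generate_phantom(p)
      out[[k]] <- list(image = ph$image, truth = ph$truth,
                       label = g$label, id = sprintf("%s_%02d", g$label, j))
    }
  }
  out
}

#' Default four-group cohort design
#'
#' Group sizes of the reference study design: a bile-salt positive control
#' (DHC, n = 8) with strong barrier opening, against sham (n = 6),
#' endothelin-1 (n = 7) and remote spreading-depolarization (n = 5) arms
#' without leakage.
#'
#' @param dhc_ratio leak ratio of the positive-control arm.
#' @return a data.frame with columns `label`, `n`, `leak_ratio`.
#' @export
default_group_specs <- function(dhc_ratio = 1.6) {
  data.frame(label = c("DHC", "sham", "ET1", "SD"),
             n = c(8L, 6L, 7L, 5L),
             leak_ratio = c(dhc_ratio, 1, 1, 1),
             stringsAsFactors = FALSE)
}
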