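# Shared fixtures: scaled-down phantoms keep the suite fast while
# preserving the geometry (leak disc inside the upper ROI, square inside
# the disc).

small_phantom <- function(leak_ratio = 1, noise_sd = 0, seed = 1,
                          scale = 0.25, ...) {
  generate_phantom(phantom_params(rows = round(1040 * scale),
                                  cols = round(1392 * scale),
                                  leak_ratio = leak_ratio,
                                  noise_sd = noise_sd, seed = seed, ...))
}

# square side scaled like the phantom so it stays inside the leak disc
side_for <- function(scale) max(4L, round(50 * scale))

assess_phantom <- function(ph, scale = 0.25, mode = "intensity", ...) {
  assess_image(ph$image, ph$truth$seed_point,
               cfg = filter_config(mode, ...),
               side = side_for(scale))
}

mirror_slice <- function(img) {
  slice_image(img$pixels[, dim(img$pixels)[2]:1, , drop = FALSE],
              img$bit_depth, "mirrored")
}

# full pipeline TBR of a cohort entry list (from generate_cohort)
cohort_tbrs <- function(cohort, scale) {
  vals <- vapply(cohort, function(e) {
    assess_image(e$image, e$truth$seed_point,
                 cfg = filter_config("intensity"),
                 side = side_for(scale))$result$tbr
  }, numeric(1))
  split(vals, vapply(cohort, function(e) e$label, character(1)))
}
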