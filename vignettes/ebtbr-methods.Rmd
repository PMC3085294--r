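---
title: "Methods: semiquantitative Evans blue extravasation assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semiquantitative Evans blue extravasation assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its model

Evans blue binds serum albumin with high affinity. With an intact
blood–brain barrier (BBB) the complex stays in the vasculature, so blue
staining of brain parenchyma in a coronal slice photographed *ex vivo*
marks where the barrier opened. `ebtbr` quantifies this with a
**target-to-background ratio (TBR)** per animal:

$$
\mathrm{TBR} \;=\;
\frac{\tilde m_\mathrm{target} / \tilde m_\mathrm{norm,ipsi}}
     {\tilde m_\mathrm{background} / \tilde m_\mathrm{norm,contra}},
$$

where each $\tilde m$ is the median blue-channel intensity of a
50 × 50 px square: *target* under the cranial window, *background* at the
mirrored position in the contralateral hemisphere, and one bottom
*normalization* square per hemisphere, outside the region of interest.
Medians (not means) make each square's value robust to specks, vessels
and outline pixels; the per-hemisphere normalization removes residual
left–right illumination differences; the final ratio removes any global
gain. The statistic is deliberately **relative**: it cannot, and does not
try to, estimate absolute dye concentration.

The assumptions this rests on:

* blue-channel intensity increases monotonically (approximately
  proportionally) with local dye content;
* the contralateral hemisphere is an anatomically homologous,
  untreated control, so its mirrored square samples equivalent tissue;
* illumination differs between images at most affinely (gain + offset),
  which the full-range rescaling and the ratio structure cancel;
* the bottom of the slice is remote enough from the window that its
  squares are unaffected by the treatment.

## Pipeline stages and their parameters

**Channel extraction and rescaling.** The blue plane of the RGB image is
taken as the measurement channel; 8-bit inputs are promoted by ×257 so
255 maps exactly to 65535. The channel is then linearly rescaled so its
observed minimum is 0 and its maximum 65535 — the largest uint16 value;
the map rounds to integers, is idempotent, and is invariant under
positive affine transforms of the input. Rescaling the *whole* image
(not only brain pixels) is the implemented choice; on a dark-field
photograph the image minimum is background, so the rescale anchors the
offset there.

**Segmentation.** Three alternative filters produce the binary brain
mask, because image quality dictates which works best on a given slice:

* `intensity`: foreground at or above `intensity_threshold`
  (Otsu's threshold when unset), specks below `min_object_area`
  (default 64 px) removed, interior holes filled;
* `gradient`: the central-difference gradient magnitude
  (replicate-padded at borders) thresholded at `gradient_threshold`
  gives an edge band; the enclosed region is filled. Central differences
  respond one pixel on *both* sides of an edge, so the filled region is
  eroded by one pixel (4-neighbour diamond) to re-centre the boundary —
  this makes a sharp-edged rectangle come back pixel-exact. If the band
  encloses nothing the filter fails with an open-contour error rather
  than guessing;
* `canny`: Gaussian smoothing at `canny_sigma` (default 2 px),
  gradient magnitude/direction, non-maximum suppression over four
  quantized directions, hysteresis with `canny_low < canny_high`
  (defaults derived from the suppressed magnitude: high = half its
  maximum, low = 0.4 high). Broken contours are *interpolated* by
  morphological closing with a disc of `closing_radius` (default 5 px),
  the enclosed region filled, and the largest connected component kept —
  one brain per slice.

Thresholds are per-image settings, as in the original assay where they
were tuned manually to image quality; batch configs carry them per image.

**Geometry.** The channel is cropped to the mask's tight bounding box;
the upper `fraction` (default 0.20, rows `1..ceiling(fraction * rows)`)
of the cutout is the ROI approximating cortex between surface and
ventricles. The target square is centred on the user seed (clamped
inward if needed, with a warning) and must intersect the ROI; the
background square is its horizontal mirror about the cutout's vertical
midline (`col_bg = cols - col_target - side + 2` in 1-based
coordinates); the normalization squares share the two columns and sit in
the bottom band, `margin` (default 5 px) above the lower edge. The
target position is also stored as distances to the cutout edges, so a
placement replays exactly without the interactive seed. Coordinates are
1-based `(row, col)`, row 1 at the top, squares spanning closed
`side`-pixel ranges — the idiomatic R convention, applied uniformly so no
module mixes origins. Two geometric subtleties are intentional:

* mirroring is defined on the *square* (box mirror), which is exact for
  every side length; re-centering a square at a mirrored seed is
  equivalent only for odd sides, since an even square is half a pixel
  asymmetric about its centre pixel;
* squares are not required to contain only mask-foreground pixels (the
  bottom squares of a convex slice often straddle the outline); instead,
  mask-background pixels are excluded from the median and their count
  logged. This keeps zeroed background from dragging medians down.

**Statistics.** Per-animal TBRs are compared with the Kruskal–Wallis
ANOVA on ranks (tie-corrected H, chi-square approximation; exact
permutation p by exhaustive enumeration available for total n ≤ 12) and
Dunn's post hoc pairwise z tests on mean ranks with tie-corrected pooled
variance. Dunn's classical multiplicity control is Bonferroni over all
k(k−1)/2 pairs; that is the default, with `adjust = "none"` available.
All tests are two-sided; ties get mid-ranks. The two-group case uses the
Mann–Whitney rank sum test, exact (full permutation distribution) when
the smaller sample has ≤ 8 observations and no ties, otherwise the
normal approximation with tie correction and continuity correction.
Summaries report median and first/third quartiles per group.

## The phantom generator

`generate_phantom()` builds the study's conditions synthetically so every
stage is testable without animal data: a bright ellipse (default
semi-axes 0.35 × rows, 0.40 × cols — a brain-like fill of the default
1040 × 1392 frame) on a dark background; an optional leak disc in the
upper part of the right hemisphere, inside the upper-20% ROI, whose blue
intensity is `leak_ratio` × the tissue level; red/green planes as
attenuated copies; a global affine illumination perturbation; additive
Gaussian noise (default sd 2% of the 16-bit range) clipped to
[0, 65535]. The background level defaults to 0: slices are photographed
against a dark field, and with a proportional intensity model the
constructed `leak_ratio` is then exactly the ratio the pipeline should
recover, making it a direct recovery target. `generate_cohort()` adds
per-animal jitter (±3% on geometry, staining level and gain, a small
illumination offset and leak-centre displacement) and emulates the
four-arm reference design: a positive-control arm with strong leakage
(n = 8) against sham (n = 6), ET-1 (n = 7) and remote-SD (n = 5) arms
without.

What the phantoms do **not** emulate: anatomical texture (ventricles,
vasculature, hemispheric fissure), irregular slice outlines, specular
highlights, chromatic effects of fixation, and graded leak borders.
Passing the synthetic suite therefore demonstrates that the *algorithm*
is correct and self-consistent (ratio recovery, symmetry, invariances,
segmentation against known truth) — not that segmentation thresholds
transfer to any particular camera or staining protocol; those remain
per-image choices, as in the original assay.

## Numerical and design choices

* **65535, not 2¹⁶**: the rescale ceiling is the largest representable
  uint16 value.
* **ceil rule** for the ROI: `n_rows = ceiling(fraction * rows)`, so a
  formally 20% band never rounds to zero rows.
* **Even-count medians** are the mean of the two central order
  statistics (`stats::median`).
* **Degenerate inputs fail loudly**: constant images (rescaling
  undefined), empty masks, open contours, zero square medians (TBR
  undefined) and identical-data rank tests all raise classed errors
  rather than returning NaN.
* **Determinism**: phantoms are seeded and restore the caller's RNG
  state; batch runs write identical bytes on reruns; placement is a pure
  function of (mask, seed, side, fraction, margin).
* **Normalizers**: the per-hemisphere rule is the default; a
  `single_normalizer` switch normalizes both sides by the ipsilateral
  bottom square, the other reading of the assay's description.

## Power at the reference group sizes

With group sizes 8/6/7/5 and a strong leak effect, the leak arm occupies
the top 8 ranks of 26 essentially always, so Kruskal–Wallis rejects in
every replicate. The Bonferroni-adjusted Dunn comparison of the leak arm
against a specific null arm is harder: conditional on the leak arm
ranking on top, the flag depends only on how the 18 exchangeable null
animals happen to order, and the exact combinatorial probability that
sham's mean rank clears the adjusted critical z is 0.875. That ceiling is
a property of the design (six comparisons at these sample sizes), not of
effect size, noise level, or implementation — a useful reminder that a
"significant omnibus + per-pair post hoc" claim at n ≤ 8 per arm is
fragile. The suite's cohort checks compute these rates over 100 seeded
replicates at 1/10 image scale (104 × 140 px, squares scaled to
10 px), where TBR recovery is unchanged and a replicate costs well under
a second.

## Problem sizes used by tests

Unit tests run phantoms at 1/10 to 1/2 of the acquisition frame
(choosing the scale per check; the square side scales with the frame so
it stays inside the leak disc), with the full 1040 × 1392 frame
exercised for the read-back, symmetry and ratio-recovery identities.
Exact-enumeration oracles are evaluated at total n ≤ 10.

## Known limitations

* One brain per image; touching debris is rejected only by the
  largest-component rule in Canny mode and the speck filter elsewhere.
* The gradient filter is brittle on noisy, low-contrast edges by
  construction (no smoothing stage); the Canny mode exists for exactly
  that case.
* The contralateral mirror assumes the slice is photographed reasonably
  level; a strongly rotated slice would need prior rectification, which
  the package does not provide.
* Physical units (mm²) are not recovered; square sizes are chosen in
  pixels for a given magnification.
* TBR thresholds for calling a barrier "open" are not defined — the
  statistic is designed for group comparisons, not per-animal
  classification.
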