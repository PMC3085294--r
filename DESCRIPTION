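Package: ebtbr
Title: Semiquantitative Evans Blue Extravasation Assessment in Brain-Slice Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for ex vivo assessment of blood-brain
    barrier permeability from coronal brain-slice photographs stained with
    Evans blue. The blue channel of each RGB image is rescaled to the full
    16-bit range, the brain is segmented from the background by intensity,
    gradient, or Canny edge filters, and four 50x50-pixel measurement
    squares (target, contralateral background, and two bottom normalization
    squares) yield a target-to-background ratio (TBR) of median blue
    intensity. Includes a synthetic phantom generator with ground-truth
    masks and leak ratios, nonparametric group statistics (Kruskal-Wallis
    with Dunn's post hoc test, Mann-Whitney with exact small-sample
    p-values), and a batch command-line interface driven by YAML configs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
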