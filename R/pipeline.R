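# Batch orchestration: a declarative YAML config drives the whole pipeline
# (images -> masks -> placements -> TBRs -> statistics -> overlays and
# reports), so the manual choices of the assay — per-image filter
# thresholds, the seed point in the cranial-window centre, the ROI
# fraction — are recorded and every run is replayable.

#' Read a run configuration
#'
#' The YAML file holds global settings (`output_dir`, `roi_fraction`,
#' `square_side`, `norm_margin`, `single_normalizer`, `rescale`, a default
#' `filter` block) and an `images` list; each image entry needs `path` and
#' `seed` (`[row, col]`, full-image coordinates) and may carry `id`,
#' `group` and a per-image `filter` override block. Relative image paths
#' are resolved against the config file's directory.
#'
#' @param path path to a YAML config.
#' @return a validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    ebtbr_error(sprintf("config file not found: %s", path),
                "ebtbr_config_error")
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    ebtbr_error(sprintf("cannot parse config %s: %s", path,
                        conditionMessage(e)), "ebtbr_config_error"))
  cfg$roi_fraction <- cfg$roi_fraction %||% 0.20
  cfg$square_side <- cfg$square_side %||% 50
  cfg$norm_margin <- cfg$norm_margin %||% 5
  cfg$single_normalizer <- isTRUE(cfg$single_normalizer)
  cfg$rescale <- cfg$rescale %||% TRUE
  cfg$output_dir <- cfg$output_dir %||% "ebtbr_out"
  if (is.null(cfg$images) || length(cfg$images) == 0)
    ebtbr_error("config lists no images", "ebtbr_config_error")
  base <- dirname(normalizePath(path))
  for (i in seq_along(cfg$images)) {
    entry <- cfg$images[[i]]
    if (is.null(entry$path))
      ebtbr_error(sprintf("images[%d]: missing 'path'", i),
                  "ebtbr_config_error")
    if (is.null(entry$seed) || length(entry$seed) != 2)
      ebtbr_error(sprintf(
        "images[%d] (%s): exactly one seed point [row, col] is required",
        i, entry$path), "ebtbr_config_error")
    if (!grepl("^(/|[A-Za-z]:)", entry$path))
      cfg$images[[i]]$path <- file.path(base, entry$path)
  }
  cfg
}

build_filter <- function(lst, defaults = NULL) {
  if (is.null(lst) && is.null(defaults)) return(filter_config())
  merged <- defaults %||% list()
  for (nm in names(lst)) merged[[nm]] <- lst[[nm]]
  do.call(filter_config, merged)
}

placement_json <- function(id, group, sq, offset) {
  jsonlite::toJSON(list(
    id = id, group = group, side = sq$side,
    cutout_offset = unname(offset),
    target = unname(sq$target), background = unname(sq$background),
    norm_ipsi = unname(sq$norm_ipsi), norm_contra = unname(sq$norm_contra),
    seed_distances = as.list(sq$seed_distances),
    fg_fraction = as.list(round(sq$fg_fraction, 4))),
    auto_unbox = TRUE, digits = NA)
}

#' Assess a batch of slice images from a config
#'
#' Runs the full pipeline over every image in the config, writing per-image
#' mask and overlay PNGs, a `results.csv` (one row per animal: id, group,
#' the four medians, both relative values, TBR), a `placements.jsonl` with
#' full placement provenance, and — when at least two groups succeed — a
#' statistics report (`report.txt` and `report.json`): Mann-Whitney for two
#' groups, Kruskal-Wallis with Dunn's post hoc analysis for three or more.
#' Failures are row-scoped: a broken image is recorded in the `error`
#' column and the batch continues.
#'
#' @param config path to a YAML config or a list as returned by
#'   [read_run_config()].
#' @param output_dir overrides the config's output directory.
#' @param alpha significance level for the report.
#' @return invisibly, a list with `results` (data.frame), `reports`,
#'   `output_dir` and `n_failed`. Errors with class `ebtbr_batch_error` if
#'   zero images succeed.
#' @export
run_assess <- function(config, output_dir = NULL, alpha = 0.05) {
  if (is.character(config)) config <- read_run_config(config)
  out <- output_dir %||% config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  default_filter <- config$filter
  results <- list()
  jsonl <- character(0)
  for (i in seq_along(config$images)) {
    entry <- config$images[[i]]
    id <- entry$id %||% tools::file_path_sans_ext(basename(entry$path))
    group <- entry$group %||% ""
    row <- tryCatch({
      fcfg <- build_filter(entry$filter, default_filter)
      a <- assess_image(entry$path, unlist(entry$seed), cfg = fcfg,
                        roi_fraction = config$roi_fraction,
                        side = config$square_side,
                        margin = config$norm_margin,
                        single_normalizer = config$single_normalizer,
                        rescale = config$rescale,
                        animal_id = id, group_label = group)
      write_image(a$mask$pixels * 255, file.path(out, paste0(id, "_mask.png")),
                  bit_depth = 8L)
      write_image(render_overlay(a$cutout, a$placement),
                  file.path(out, paste0(id, "_overlay.png")))
      jsonl <- c(jsonl, placement_json(id, group, a$placement,
                                       a$cutout$offset))
      cbind(as.data.frame(a$result), error = NA_character_,
            stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(animal_id = id, group = group,
                 median_target = NA_real_, median_background = NA_real_,
                 median_norm_ipsi = NA_real_, median_norm_contra = NA_real_,
                 rel_ipsi = NA_real_, rel_contra = NA_real_, tbr = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    results[[i]] <- row
  }
  results <- do.call(rbind, results)
  write.csv(results, file.path(out, "results.csv"), row.names = FALSE)
  writeLines(jsonl, file.path(out, "placements.jsonl"))
  ok <- results[is.na(results$error), ]
  if (nrow(ok) == 0)
    ebtbr_error("no image in the batch could be assessed",
                "ebtbr_batch_error")
  reports <- NULL
  grp_tab <- table(ok$group[nzchar(ok$group)])
  if (length(grp_tab) >= 2) {
    groups <- split(ok$tbr[nzchar(ok$group)], ok$group[nzchar(ok$group)])
    reports <- tryCatch(tbr_report(groups, alpha = alpha),
                        ebtbr_error = function(e) NULL)
    if (!is.null(reports)) write_report(reports, out)
  }
  invisible(list(results = results, reports = reports, output_dir = out,
                 n_failed = sum(!is.na(results$error))))
}

#' Group statistics over TBR values
#'
#' @param groups named list of per-group TBR vectors.
#' @param alpha significance level.
#' @return list of `test_report`s: `kruskal_wallis` and `dunn` for three
#'   or more groups, `mann_whitney` for exactly two.
#' @export
tbr_report <- function(groups, alpha = 0.05) {
  if (length(groups) >= 3)
    list(kruskal_wallis = kruskal_wallis(groups),
         dunn = dunn_posthoc(groups, alpha = alpha))
  else
    list(mann_whitney = mann_whitney(groups[[1]], groups[[2]]))
}

write_report <- function(reports, out) {
  txt <- file.path(out, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  for (r in reports) {
    sink(con)
    print(r)
    sink()
  }
  json <- lapply(reports, function(r) {
    r$groups <- NULL
    unclass(r)
  })
  jsonlite::write_json(json, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(txt)
}

#' Simulate a phantom cohort and write it to disk
#'
#' Generates a cohort with [generate_cohort()], writes each phantom as a
#' 16-bit TIFF plus its ground-truth mask (PNG), a `truth.csv`
#' (id, group, true_ratio, seed point, RNG seed), and a ready-to-use
#' assess config pointing at the files, with each image's seed point set
#' to the phantom's leak centre.
#'
#' @param output_dir directory to populate.
#' @param group_specs,shared,seed,jitter passed to [generate_cohort()].
#' @param square_side square side written into the config; scale it with
#'   the phantom size (50 at full 1040 x 1392 scale).
#' @return invisibly, the path of the written config.
#' @export
run_simulate <- function(output_dir, group_specs = default_group_specs(),
                         shared = phantom_params(), seed = 1L,
                         jitter = 0.03,
                         square_side = max(4L, round(50 * shared$rows / 1040))) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(group_specs, shared, seed = seed,
                            jitter = jitter)
  truth_rows <- list()
  images <- list()
  for (entry in cohort) {
    fn <- paste0(entry$id, ".tif")
    write_image(entry$image, file.path(output_dir, fn))
    write_image(entry$truth$mask * 255,
                file.path(output_dir, paste0(entry$id, "_truth_mask.png")),
                bit_depth = 8L)
    sp <- entry$truth$seed_point
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      id = entry$id, group = entry$label,
      true_ratio = entry$truth$true_ratio,
      seed_row = sp[1], seed_col = sp[2],
      rng_seed = entry$truth$params$seed, stringsAsFactors = FALSE)
    images[[length(images) + 1]] <- list(path = fn, id = entry$id,
                                         group = entry$label,
                                         seed = c(sp[1], sp[2]))
  }
  write.csv(do.call(rbind, truth_rows), file.path(output_dir, "truth.csv"),
            row.names = FALSE)
  cfg <- list(output_dir = file.path(output_dir, "assessment"),
              roi_fraction = 0.20, square_side = square_side,
              norm_margin = 5,
              filter = list(mode = "intensity"),
              images = images)
  cfg_path <- file.path(output_dir, "assess_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
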