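#' Pipeline stages
#'
#' Thin orchestration over the simulation, scoring, and characterization
#' functions: each stage resolves its inputs, writes its outputs as TSV under
#' `out_dir`, and logs a JSON run manifest (resolved configuration, seed,
#' paths, package version, timestamp) so a run can be reproduced
#' bit-for-bit from its manifest.
#'
#' @name pipeline
NULL

write_manifest <- function(out_dir, command, config, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    tool_version = as.character(utils::packageVersion("modscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Simulate a screen (and optionally a cell table) to disk
#'
#' @param config Path to a YAML configuration file (see [read_config()]), or
#'   the list returned by it.
#' @param out_dir Output directory, created if needed.
#' @param seed Optional integer overriding the config's seed(s).
#' @return Invisibly, a named character vector of output paths.
#' @rdname pipeline
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (!is.null(seed)) {
    cfg$screen$seed <- as.integer(seed)
    if (!is.null(cfg$cells)) cfg$cells$seed <- as.integer(seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- simulate_screen(cfg$screen)
  paths <- c(animals = file.path(out_dir, "animals.tsv"),
             crosses = file.path(out_dir, "crosses.tsv"))
  write_screen_tsv(dataset, paths["animals"], paths["crosses"])
  if (!is.null(cfg$cells)) {
    cells <- simulate_cell_table(cfg$cells)
    paths["cells"] <- file.path(out_dir, "cells.tsv")
    write_cells_tsv(cells, paths[["cells"]])
  }
  write_manifest(out_dir, "simulate",
                 config = lapply(cfg, unclass),
                 seed = cfg$screen$seed,
                 inputs = if (is.character(config)) config else NULL,
                 outputs = as.list(paths))
  invisible(paths)
}

#' Analyze a screen TSV: score, summarize, classify
#'
#' @param animals_path Per-animal TSV (the dialect of [write_screen_tsv()]).
#' @param crosses_path Optional per-cross TSV (needed to report
#'   synthetic-lethal crosses, which leave no animals).
#' @param threshold Classification threshold in control-SD units.
#' @param min_n Minimum intended sample size for the `low_n` flag.
#' @rdname pipeline
#' @export
run_analyze <- function(animals_path, out_dir, crosses_path = NULL,
                        threshold = 1, min_n = 15) {
  dataset <- read_screen_tsv(animals_path, crosses_path)
  scored <- score_screen(dataset)
  summaries <- analyze_screen(dataset, threshold = threshold, min_n = min_n)
  counts <- classification_counts(summaries)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scored = file.path(out_dir, "animals_scored.tsv"),
             genotypes = file.path(out_dir, "genotype_summaries.tsv"),
             counts = file.path(out_dir, "classification_counts.tsv"))
  write_scored_tsv(scored, paths[["scored"]])
  readr::write_tsv(summaries, paths[["genotypes"]])
  readr::write_tsv(counts, paths[["counts"]])
  write_manifest(out_dir, "analyze",
                 config = list(threshold = threshold, min_n = min_n),
                 seed = NULL,
                 inputs = list(animals = animals_path, crosses = crosses_path),
                 outputs = as.list(paths))
  invisible(paths)
}

#' Estimate operating characteristics of the rule to disk
#'
#' @param effect_grid Positive effect multipliers to profile.
#' @param n_reps Replicate screens per effect level.
#' @rdname pipeline
#' @export
run_characterize <- function(config, out_dir, effect_grid = c(1, 2, 4, 8),
                             n_reps = 20, threshold = 1, min_n = 15,
                             seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (!is.null(seed)) cfg$screen$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  oc <- power_curve(cfg$screen, effect_grid = effect_grid, n_reps = n_reps,
                    threshold = threshold, min_n = min_n)
  path <- file.path(out_dir, "operating_characteristics.tsv")
  readr::write_tsv(oc$power_by_effect, path)
  write_manifest(out_dir, "characterize",
                 config = list(screen = unclass(cfg$screen),
                               effect_grid = effect_grid, n_reps = n_reps,
                               threshold = threshold, min_n = min_n),
                 seed = cfg$screen$seed,
                 inputs = if (is.character(config)) config else NULL,
                 outputs = list(operating_characteristics = path))
  invisible(oc)
}

#' Quantify a per-cell table to disk
#'
#' @param cells_path Per-cell TSV.
#' @rdname pipeline
#' @export
run_cellquant <- function(cells_path, out_dir, var_equal = TRUE) {
  cells <- read_cells_tsv(cells_path)
  comparison <- normalize_intensities(cells, var_equal = var_equal)
  edu <- edu_fraction(cells)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(comparison = file.path(out_dir, "intensity_comparison.tsv"),
             edu = file.path(out_dir, "edu_fractions.tsv"))
  readr::write_tsv(comparison, paths[["comparison"]])
  readr::write_tsv(edu, paths[["edu"]])
  write_manifest(out_dir, "cellquant",
                 config = list(var_equal = var_equal), seed = NULL,
                 inputs = list(cells = cells_path), outputs = as.list(paths))
  invisible(paths)
}
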