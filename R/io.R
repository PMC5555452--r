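#' Write and read screen datasets as TSV
#'
#' The canonical on-disk dialect is UTF-8 TSV with a mandatory header. The
#' per-animal table serializes the tumor-size list as semicolon-joined
#' decimals (empty string for a tumor-free animal); the per-cross table
#' carries progeny counts, lethality flags, and — for simulated screens —
#' the ground-truth effect multiplier.
#'
#' @param dataset A `screen_dataset` (or a list with `animals` and `crosses`
#'   tibbles).
#' @param animals_path,crosses_path Output TSV paths.
#' @return Invisibly, the paths written.
#' @export
write_screen_tsv <- function(dataset, animals_path, crosses_path) {
  animals <- dataset$animals
  flat <- tibble::tibble(
    animal_id = animals$animal_id,
    genotype_id = animals$genotype_id,
    batch_id = animals$batch_id,
    role = animals$role,
    tumor_sizes = vapply(animals$tumor_sizes, function(s)
      paste(format(s, trim = TRUE, scientific = FALSE), collapse = ";"),
      character(1))
  )
  extra <- setdiff(names(animals), c(names(flat), "tumor_sizes"))
  for (col in extra) flat[[col]] <- animals[[col]]
  readr::write_tsv(flat, animals_path)
  readr::write_tsv(dataset$crosses, crosses_path)
  invisible(c(animals_path, crosses_path))
}

#' @rdname write_screen_tsv
#' @return `read_screen_tsv()` returns a `screen_dataset` (without a config).
#' @export
read_screen_tsv <- function(animals_path, crosses_path = NULL) {
  flat <- readr::read_tsv(animals_path, col_types = readr::cols(
    animal_id = readr::col_character(),
    genotype_id = readr::col_character(),
    batch_id = readr::col_character(),
    role = readr::col_character(),
    tumor_sizes = readr::col_character(),
    .default = readr::col_double()
  ))
  flat$tumor_sizes[is.na(flat$tumor_sizes)] <- ""
  animals <- flat
  animals$tumor_sizes <- lapply(flat$tumor_sizes, function(s) {
    if (!nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  crosses <- NULL
  if (!is.null(crosses_path)) {
    crosses <- readr::read_tsv(crosses_path, col_types = readr::cols(
      genotype_id = readr::col_character(),
      batch_id = readr::col_character(),
      role = readr::col_character(),
      n_progeny = readr::col_integer(),
      lethal = readr::col_logical(),
      true_effect = readr::col_double()
    ))
  }
  structure(list(animals = animals, crosses = crosses, config = NULL),
            class = "screen_dataset")
}

#' Write scored per-animal table (with TI and NTI columns) as TSV
#'
#' @param scored Output of [score_screen()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_scored_tsv <- function(scored, path) {
  flat <- scored
  flat$tumor_sizes <- vapply(scored$tumor_sizes, function(s)
    paste(format(s, trim = TRUE, scientific = FALSE), collapse = ";"), character(1))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Write and read per-cell measurement tables as TSV
#'
#' @param cells Per-cell tibble (`cell_id`, `group`, `gray_value`, `p1`,
#'   `l1`, `edu`).
#' @param path TSV path.
#' @return Invisibly the path; `read_cells_tsv()` returns the tibble.
#' @export
write_cells_tsv <- function(cells, path) {
  readr::write_tsv(cells, path)
  invisible(path)
}

#' @rdname write_cells_tsv
#' @export
read_cells_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cell_id = readr::col_character(),
    group = readr::col_character(),
    gray_value = readr::col_double(),
    p1 = readr::col_logical(),
    l1 = readr::col_logical(),
    edu = readr::col_logical()
  ))
}
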