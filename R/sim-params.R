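#' Simulation parameters for one cross
#'
#' Bundles the per-cross generative model: an animal develops at least one
#' melanotic tumor with probability `penetrance`; an affected animal carries
#' a zero-truncated Poisson number of tumors with rate
#' `tumor_count_mean * effect_multiplier`; each tumor's size is `0.25 * g`
#' with `g` geometric on \{1, 2, ...\} (success probability `size_param`),
#' so all sizes lie on the quarter-abdominal-segment grid used for scoring.
#'
#' Temperature enters only through presets: `preset = "25C"` sets penetrance
#' to 0.68, `preset = "29C"` to 0.99, matching the observed penetrance of the
#' sensitized JAK gain-of-function background at those rearing temperatures.
#'
#' @param penetrance Probability in `[0, 1]` that an animal develops >= 1
#'   tumor.
#' @param tumor_count_mean Positive Poisson rate (before zero-truncation) for
#'   the tumor count of an affected animal.
#' @param size_param Success probability in `(0, 1]` of the geometric
#'   distribution over quarter-segment size steps. `size_param = 1` forces
#'   every tumor to size 0.25.
#' @param effect_multiplier Positive multiplicative shift applied to
#'   `tumor_count_mean` for a modifier genotype; 1 means no effect.
#' @param penetrance_shift Optional additive shift applied to `penetrance`
#'   (clamped to `[0, 1]`), exposed because a modifier could act on
#'   penetrance rather than burden; default 0.
#' @param n_per_cross Integer >= 1, number of scored F1 progeny per cross.
#' @param lethal Logical; `TRUE` marks a synthetic-lethal cross that yields
#'   zero progeny regardless of `n_per_cross`.
#' @param preset Optional temperature preset, `"25C"` or `"29C"`; overrides
#'   `penetrance`.
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' sim_params()                    # 25 degree defaults
#' sim_params(preset = "29C")      # near-complete penetrance
sim_params <- function(penetrance = 0.68,
                       tumor_count_mean = 2,
                       size_param = 0.5,
                       effect_multiplier = 1,
                       penetrance_shift = 0,
                       n_per_cross = 15L,
                       lethal = FALSE,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("25C", "29C"))
    penetrance <- switch(preset, "25C" = 0.68, "29C" = 0.99)
  }
  p <- structure(
    list(
      penetrance = penetrance,
      tumor_count_mean = tumor_count_mean,
      size_param = size_param,
      effect_multiplier = effect_multiplier,
      penetrance_shift = penetrance_shift,
      n_per_cross = as.integer(n_per_cross),
      lethal = isTRUE(lethal)
    ),
    class = "sim_params"
  )
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  check <- function(ok, msg) if (!ok) stop("invalid sim_params: ", msg, call. = FALSE)
  check(is.numeric(p$penetrance) && length(p$penetrance) == 1 &&
          p$penetrance >= 0 && p$penetrance <= 1,
        "penetrance must be a probability in [0, 1]")
  check(is.numeric(p$tumor_count_mean) && p$tumor_count_mean > 0,
        "tumor_count_mean must be > 0")
  check(is.numeric(p$size_param) && p$size_param > 0 && p$size_param <= 1,
        "size_param must be in (0, 1]")
  check(is.numeric(p$effect_multiplier) && p$effect_multiplier > 0,
        "effect_multiplier must be > 0")
  check(is.numeric(p$penetrance_shift) && abs(p$penetrance_shift) <= 1,
        "penetrance_shift must be in [-1, 1]")
  check(is.integer(p$n_per_cross) && !is.na(p$n_per_cross) && p$n_per_cross >= 1,
        "n_per_cross must be an integer >= 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  penetrance        %.3f (shift %+.3f)\n", x$penetrance, x$penetrance_shift))
  cat(sprintf("  tumor_count_mean  %.3f x effect %.3f\n", x$tumor_count_mean, x$effect_multiplier))
  cat(sprintf("  size_param        %.3f\n", x$size_param))
  cat(sprintf("  n_per_cross       %d%s\n", x$n_per_cross, if (x$lethal) "  [synthetic lethal]" else ""))
  invisible(x)
}

#' Configuration of a full modifier screen
#'
#' Describes a screen of `n_df` deficiency (Df) crosses divided into batches;
#' every batch is paired with exactly one control outcross simulated under
#' `control_params`, mirroring a design where each batch of Dfs is set up in
#' parallel with its own control cross used for normalization.
#'
#' @param n_df Number of Df crosses (default 363, the size of a full
#'   deficiency-kit screen of chromosomes 2 and 3).
#' @param batch_size Df crosses per batch (each batch gets one control).
#' @param control_params `sim_params` for the control cross of every batch;
#'   also the base parameters of every Df cross before its effect is applied.
#' @param df_effects Named numeric vector mapping genotype ids to effect
#'   multipliers; genotypes not named default to 1 (null). An entry of `NA`
#'   marks a synthetic-lethal cross.
#' @param seed Integer master seed; per-cross random streams are derived from
#'   it so adding a cross does not perturb earlier ones.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_df = 363L,
                          batch_size = 20L,
                          control_params = sim_params(),
                          df_effects = NULL,
                          seed = 1L) {
  cfg <- structure(
    list(
      n_df = as.integer(n_df),
      batch_size = as.integer(batch_size),
      control_params = control_params,
      df_effects = df_effects,
      seed = as.integer(seed)
    ),
    class = "screen_config"
  )
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  stopifnot(inherits(cfg, "screen_config"))
  if (is.na(cfg$n_df) || cfg$n_df < 1) stop("invalid screen_config: n_df must be >= 1", call. = FALSE)
  if (is.na(cfg$batch_size) || cfg$batch_size < 1) stop("invalid screen_config: batch_size must be >= 1", call. = FALSE)
  validate_sim_params(cfg$control_params)
  if (!is.null(cfg$df_effects)) {
    if (is.null(names(cfg$df_effects)) || any(!nzchar(names(cfg$df_effects))))
      stop("invalid screen_config: df_effects must be a named vector", call. = FALSE)
    bad <- !is.na(cfg$df_effects) & cfg$df_effects <= 0
    if (any(bad)) stop("invalid screen_config: effect multipliers must be > 0 (NA marks lethality)", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("invalid screen_config: seed must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  n_batches <- ceiling(x$n_df / x$batch_size)
  cat(sprintf("<screen_config> %d Df crosses in %d batches of <= %d, seed %d\n",
              x$n_df, n_batches, x$batch_size, x$seed))
  n_eff <- if (is.null(x$df_effects)) 0L else sum(is.na(x$df_effects) | x$df_effects != 1)
  cat(sprintf("  non-null planted effects: %d\n", n_eff))
  invisible(x)
}

#' Parameters for a simulated per-cell measurement table
#'
#' Emulates a mixed-cell slide: reference (control) cells and experimental
#' cells measured under identical staining, with per-cell mean gray values
#' drawn from a normal distribution truncated at zero and marker flags
#' (P1, L1, EdU) drawn independently per cell.
#'
#' @param n_cells_control,n_cells_exp Integers >= 2.
#' @param control_mean,control_sd Gray-value units; `control_sd > 0`.
#' @param effect_ratio Positive scalar multiplying `control_mean` (and the
#'   SD, so the coefficient of variation is preserved) for the experimental
#'   group.
#' @param p1_fraction Probability a cell is P1-positive (plasmatocyte).
#' @param l1_fraction Probability a cell is L1-positive (lamellocyte).
#' @param edu_rate_control,edu_rate_exp Probability a P1-positive cell is in
#'   S phase (EdU-positive) in each group; P1-negative cells are never
#'   scored EdU-positive.
#' @param seed Integer seed.
#' @return An object of class `cell_sim_params`.
#' @export
cell_sim_params <- function(n_cells_control = 50L,
                            n_cells_exp = 50L,
                            control_mean = 100,
                            control_sd = 20,
                            effect_ratio = 1,
                            p1_fraction = 0.9,
                            l1_fraction = 0.05,
                            edu_rate_control = 0.05,
                            edu_rate_exp = 0.05,
                            seed = 1L) {
  p <- structure(
    list(
      n_cells_control = as.integer(n_cells_control),
      n_cells_exp = as.integer(n_cells_exp),
      control_mean = control_mean,
      control_sd = control_sd,
      effect_ratio = effect_ratio,
      p1_fraction = p1_fraction,
      l1_fraction = l1_fraction,
      edu_rate_control = edu_rate_control,
      edu_rate_exp = edu_rate_exp,
      seed = as.integer(seed)
    ),
    class = "cell_sim_params"
  )
  validate_cell_sim_params(p)
  p
}

validate_cell_sim_params <- function(p) {
  stopifnot(inherits(p, "cell_sim_params"))
  check <- function(ok, msg) if (!ok) stop("invalid cell_sim_params: ", msg, call. = FALSE)
  check(p$n_cells_control >= 2 && p$n_cells_exp >= 2, "need >= 2 cells per group")
  check(p$control_mean > 0, "control_mean must be > 0")
  check(p$control_sd > 0, "control_sd must be > 0")
  check(p$effect_ratio > 0, "effect_ratio must be > 0")
  for (f in c("p1_fraction", "l1_fraction", "edu_rate_control", "edu_rate_exp"))
    check(p[[f]] >= 0 && p[[f]] <= 1, paste(f, "must be in [0, 1]"))
  invisible(p)
}

#' Read simulation configuration from a YAML file
#'
#' The file holds flat key/value pairs plus nested sections `control_params`
#' (fields of [sim_params()]), `df_effects` (genotype id -> multiplier; the
#' string `"lethal"` marks synthetic lethality), and optionally `cells`
#' (fields of [cell_sim_params()]).
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `screen` (a `screen_config`) and `cells`
#'   (a `cell_sim_params` or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_top <- c("n_df", "batch_size", "seed", "control_params", "df_effects", "cells")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  cp_args <- raw$control_params %||% list()
  bad_cp <- setdiff(names(cp_args), names(formals(sim_params)))
  if (length(bad_cp))
    stop("config error: unknown control_params key(s): ", paste(bad_cp, collapse = ", "), call. = FALSE)
  control <- do.call(sim_params, cp_args)

  effects <- NULL
  if (!is.null(raw$df_effects)) {
    vals <- vapply(raw$df_effects, function(v) {
      if (identical(v, "lethal")) NA_real_ else as.numeric(v)
    }, numeric(1))
    effects <- stats::setNames(vals, names(raw$df_effects))
  }
  screen <- screen_config(
    n_df = raw$n_df %||% 363L,
    batch_size = raw$batch_size %||% 20L,
    control_params = control,
    df_effects = effects,
    seed = raw$seed %||% 1L
  )
  cells <- NULL
  if (!is.null(raw$cells)) {
    bad_cell <- setdiff(names(raw$cells), names(formals(cell_sim_params)))
    if (length(bad_cell))
      stop("config error: unknown cells key(s): ", paste(bad_cell, collapse = ", "), call. = FALSE)
    cells <- do.call(cell_sim_params, raw$cells)
  }
  list(screen = screen, cells = cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
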