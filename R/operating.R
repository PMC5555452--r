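#' Monte-Carlo false-positive rate of the classification rule
#'
#' Simulates `n_reps` replicate null screens (every Df effect = 1) under
#' `null_config`, analyzes each with the strict `|mean NTI| > threshold`
#' rule, and reports the fraction of genotype-replicates called enhancer or
#' suppressor, with an exact 95% binomial interval. Because no multiplicity
#' correction is applied in this screen design, the expected number of false
#' hits in one screen (`fpr * n_df`) is reported alongside.
#'
#' @param null_config A [screen_config()] with no planted effects (any
#'   `df_effects` entry differing from 1 is an error).
#' @param n_reps Number of replicate screens (>= 1).
#' @param threshold Classification threshold in control-SD units.
#' @param min_n Minimum intended sample size (forwarded to the analysis).
#' @return An object of class `operating_characteristics`: a list with
#'   `threshold`, `n_reps`, `n_genotype_reps`, `fpr_estimate`, `fpr_ci`
#'   (exact 95% binomial), `expected_false_hits`, and `power_by_effect`
#'   (here a single row at effect 1).
#' @export
false_positive_rate <- function(null_config, n_reps, threshold = 1, min_n = 15) {
  validate_screen_config(null_config)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.null(null_config$df_effects) &&
      any(null_config$df_effects != 1, na.rm = TRUE))
    stop("null_config must have all effects = 1", call. = FALSE)

  res <- detection_by_effect(null_config, effect_grid = 1, n_reps = n_reps,
                             threshold = threshold, min_n = min_n)
  oc(threshold, n_reps, res, null_config$n_df)
}

#' Monte-Carlo power curve of the classification rule
#'
#' For each effect multiplier in `effect_grid`, simulates `n_reps` replicate
#' screens in which every Df cross carries that effect, and reports the
#' fraction of genotype-replicates called (enhancer or suppressor). Effect 1
#' reproduces the false-positive rate.
#'
#' @param config A [screen_config()]; its `df_effects` are ignored in favor
#'   of the grid.
#' @param effect_grid Positive effect multipliers to profile.
#' @param n_reps Replicate screens per effect level.
#' @inheritParams false_positive_rate
#' @return An `operating_characteristics` object whose `power_by_effect`
#'   tibble has one row per effect level (`effect`, `power`, `ci_lower`,
#'   `ci_upper`, `n_genotype_reps`).
#' @export
power_curve <- function(config, effect_grid = c(1, 2, 4, 8), n_reps = 50,
                        threshold = 1, min_n = 15) {
  validate_screen_config(config)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (any(effect_grid <= 0)) stop("effect_grid must be positive", call. = FALSE)
  res <- detection_by_effect(config, effect_grid, n_reps, threshold, min_n)
  oc(threshold, n_reps, res, config$n_df)
}

# Shared engine: detection frequency per effect level. Each replicate screen
# gets its own seed derived from the config seed so replicates are
# independent but the whole estimate is reproducible.
detection_by_effect <- function(config, effect_grid, n_reps, threshold, min_n) {
  rep_seeds <- derive_seeds(config$seed, n_reps * length(effect_grid))
  rows <- vector("list", length(effect_grid))
  genotype_ids <- sprintf("Df_%03d", seq_len(config$n_df))
  for (j in seq_along(effect_grid)) {
    eff <- effect_grid[j]
    hits <- 0L
    total <- 0L
    for (r in seq_len(n_reps)) {
      cfg <- config
      cfg$df_effects <- stats::setNames(rep(eff, config$n_df), genotype_ids)
      cfg$seed <- rep_seeds[(j - 1L) * n_reps + r]
      sums <- analyze_screen(simulate_screen(cfg), threshold = threshold,
                             min_n = min_n)
      usable <- sums$classification %in% c("enhancer", "suppressor", "no_effect")
      hits <- hits + sum(sums$classification[usable] %in% c("enhancer", "suppressor"))
      total <- total + sum(usable)
    }
    ci <- stats::binom.test(hits, total)$conf.int
    rows[[j]] <- tibble::tibble(
      effect = eff, power = hits / total,
      ci_lower = ci[1], ci_upper = ci[2],
      n_genotype_reps = total
    )
  }
  dplyr::bind_rows(rows)
}

oc <- function(threshold, n_reps, power_by_effect, n_df) {
  null_row <- power_by_effect[power_by_effect$effect == 1, , drop = FALSE]
  fpr <- if (nrow(null_row)) null_row$power[1] else NA_real_
  structure(
    list(
      threshold = threshold,
      n_reps = n_reps,
      n_genotype_reps = sum(power_by_effect$n_genotype_reps),
      fpr_estimate = fpr,
      fpr_ci = if (nrow(null_row)) c(null_row$ci_lower[1], null_row$ci_upper[1]) else c(NA_real_, NA_real_),
      expected_false_hits = fpr * n_df,
      power_by_effect = power_by_effect
    ),
    class = "operating_characteristics"
  )
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("<operating_characteristics> threshold %.2f, %d replicate screens\n",
              x$threshold, x$n_reps))
  if (!is.na(x$fpr_estimate))
    cat(sprintf("  FPR %.4f [%.4f, %.4f]; expected false hits per screen %.2f\n",
                x$fpr_estimate, x$fpr_ci[1], x$fpr_ci[2], x$expected_false_hits))
  if (nrow(x$power_by_effect) > 1) {
    cat("  power by effect:\n")
    print(x$power_by_effect)
  }
  invisible(x)
}
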