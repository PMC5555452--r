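#' Zero-truncated Poisson deviates
#'
#' Draws from a Poisson(`lambda`) distribution conditioned on being >= 1, by
#' inverse-CDF: a uniform on `(P(X = 0), 1)` pushed through `qpois`. Exact,
#' vectorised, and stable for small `lambda` (where the law degenerates to a
#' point mass at 1).
#'
#' @param n Number of deviates.
#' @param lambda Positive rate.
#' @return Integer vector of counts >= 1.
#' @export
rztpois <- function(n, lambda) {
  stopifnot(n >= 0, lambda > 0)
  p0 <- stats::dpois(0, lambda)
  u <- stats::runif(n, min = p0, max = 1)
  k <- stats::qpois(u, lambda)
  pmax(k, 1L)
}

# Per-cross seeds derived from the master seed: one sequential draw per
# cross (replace = TRUE keeps the prefix stable when crosses are appended).
derive_seeds <- function(master_seed, n) {
  if (n == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n, replace = TRUE)
}

#' Simulate one scored F1 animal
#'
#' With probability `penetrance` (plus any `penetrance_shift`) the animal
#' carries `k >= 1` tumors, `k` zero-truncated Poisson with rate
#' `tumor_count_mean * effect_multiplier`; each tumor has size `0.25 * g`
#' with `g` geometric on \{1, 2, ...\}. Otherwise the tumor list is empty.
#' Uses the current RNG state (call `set.seed()` upstream for
#' reproducibility); [simulate_cross()] manages per-cross streams.
#'
#' @param params A [sim_params()] object.
#' @param animal_id,genotype_id,batch_id Identifiers attached to the record.
#' @return A one-row [tibble::tibble()] with columns `animal_id`,
#'   `genotype_id`, `batch_id`, and a list-column `tumor_sizes`.
#' @export
simulate_animal <- function(params, animal_id = "a1", genotype_id = "g1",
                            batch_id = "b1") {
  validate_sim_params(params)
  tibble::tibble(
    animal_id = animal_id,
    genotype_id = genotype_id,
    batch_id = batch_id,
    tumor_sizes = list(draw_tumor_sizes(1, params)[[1]])
  )
}

# Vectorised core: tumor-size lists for n animals under one parameter set.
draw_tumor_sizes <- function(n, params) {
  pen <- min(max(params$penetrance + params$penetrance_shift, 0), 1)
  affected <- stats::runif(n) < pen
  n_aff <- sum(affected)
  counts <- integer(n)
  if (n_aff > 0) {
    lambda <- params$tumor_count_mean * params$effect_multiplier
    counts[affected] <- rztpois(n_aff, lambda)
  }
  total <- sum(counts)
  sizes <- if (total > 0) 0.25 * (stats::rgeom(total, params$size_param) + 1L) else numeric(0)
  split_idx <- rep.int(seq_len(n), counts)
  out <- rep(list(numeric(0)), n)
  if (total > 0) out[unique(split_idx)] <- split(sizes, split_idx)
  out
}

#' Simulate one cross
#'
#' Returns the scored F1 progeny of a single cross: `n_per_cross` animals, or
#' an empty progeny set flagged lethal when `params$lethal` is `TRUE`.
#'
#' @param genotype_id,batch_id Identifiers for the cross.
#' @param params A [sim_params()] object.
#' @param role `"df"` for a deficiency cross, `"control"` for the paired
#'   control outcross.
#' @param seed Optional integer seed applied before drawing (the per-cross
#'   stream); if `NULL` the current RNG state is used.
#' @return A list of class `cross_result` with elements `animals` (tibble:
#'   animal_id, genotype_id, batch_id, role, tumor_sizes), `cross` (one-row
#'   tibble: genotype_id, batch_id, role, n_progeny, lethal, true_effect).
#' @export
simulate_cross <- function(genotype_id, batch_id, params, role = "df",
                           seed = NULL) {
  validate_sim_params(params)
  role <- match.arg(role, c("df", "control"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (params$lethal) {
    animals <- empty_animals(role)
    n <- 0L
  } else {
    n <- params$n_per_cross
    animals <- tibble::tibble(
      animal_id = paste0(genotype_id, "_", seq_len(n)),
      genotype_id = genotype_id,
      batch_id = batch_id,
      role = role,
      tumor_sizes = draw_tumor_sizes(n, params)
    )
  }
  cross <- tibble::tibble(
    genotype_id = genotype_id,
    batch_id = batch_id,
    role = role,
    n_progeny = n,
    lethal = params$lethal,
    true_effect = if (params$lethal) NA_real_ else params$effect_multiplier
  )
  structure(list(animals = animals, cross = cross), class = "cross_result")
}

empty_animals <- function(role = character(0)) {
  tibble::tibble(
    animal_id = character(0),
    genotype_id = character(0),
    batch_id = character(0),
    role = character(0),
    tumor_sizes = list()
  )
}

#' Simulate a full modifier screen
#'
#' Lays out `n_df` deficiency crosses into batches of at most `batch_size`,
#' pairs every batch with one control cross simulated under
#' `config$control_params`, and applies any planted effect multipliers from
#' `config$df_effects` (an `NA` entry makes the cross synthetic-lethal).
#' Every cross gets its own random stream derived from `config$seed`, so
#' results are reproducible and insensitive to the order of generation.
#'
#' @param config A [screen_config()] object.
#' @return An object of class `screen_dataset`: a list with `animals`
#'   (per-animal tibble with list-column `tumor_sizes`), `crosses`
#'   (per-cross tibble with ground-truth `true_effect` and `lethal`), and
#'   `config`.
#' @export
simulate_screen <- function(config) {
  validate_screen_config(config)
  n_df <- config$n_df
  genotype_ids <- sprintf("Df_%03d", seq_len(n_df))
  batch_ids <- sprintf("batch_%02d", ceiling(seq_len(n_df) / config$batch_size))
  batches <- unique(batch_ids)

  effects <- stats::setNames(rep(1, n_df), genotype_ids)
  if (!is.null(config$df_effects)) {
    known <- intersect(names(config$df_effects), genotype_ids)
    unknown <- setdiff(names(config$df_effects), genotype_ids)
    if (length(unknown))
      stop("df_effects names not in the screen: ", paste(unknown, collapse = ", "), call. = FALSE)
    effects[known] <- config$df_effects[known]
  }

  # One stream per cross: controls first (stable under n_df growth within
  # the last batch is not guaranteed, but Df streams are prefix-stable).
  seeds <- derive_seeds(config$seed, n_df + length(batches))
  df_seeds <- seeds[seq_len(n_df)]
  control_seeds <- stats::setNames(seeds[n_df + seq_along(batches)], batches)

  results <- vector("list", n_df + length(batches))
  for (i in seq_len(n_df)) {
    eff <- effects[[i]]
    p <- config$control_params
    if (is.na(eff)) {
      p$lethal <- TRUE
    } else {
      p$effect_multiplier <- eff
    }
    results[[i]] <- simulate_cross(genotype_ids[i], batch_ids[i], p,
                                   role = "df", seed = df_seeds[i])
  }
  for (j in seq_along(batches)) {
    ctl <- config$control_params
    ctl$effect_multiplier <- 1
    results[[n_df + j]] <- simulate_cross(
      paste0("control_", batches[j]), batches[j], ctl,
      role = "control", seed = control_seeds[[batches[j]]]
    )
  }

  structure(
    list(
      animals = dplyr::bind_rows(lapply(results, `[[`, "animals")),
      crosses = dplyr::bind_rows(lapply(results, `[[`, "cross")),
      config = config
    ),
    class = "screen_dataset"
  )
}

#' @export
print.screen_dataset <- function(x, ...) {
  n_batches <- length(unique(x$crosses$batch_id))
  cat(sprintf("<screen_dataset> %d crosses (%d Df + %d control) in %d batches, %d animals\n",
              nrow(x$crosses), sum(x$crosses$role == "df"),
              sum(x$crosses$role == "control"), n_batches, nrow(x$animals)))
  invisible(x)
}

#' Simulate a per-cell measurement table
#'
#' Emulates a mixed-cell slide: control cells (the DsRed-marked reference
#' population) with per-cell mean gray values from a normal distribution
#' truncated at zero, and experimental cells whose location (and scale) are
#' multiplied by `effect_ratio`. P1/L1 marker flags are independent
#' Bernoulli draws; EdU positivity is drawn only among P1-positive cells at
#' the group's EdU rate.
#'
#' @param params A [cell_sim_params()] object.
#' @return A tibble with columns `cell_id`, `group` (`"control"` or
#'   `"experimental"`), `gray_value`, `p1`, `l1`, `edu`.
#' @export
simulate_cell_table <- function(params) {
  validate_cell_sim_params(params)
  set.seed(params$seed)
  n_c <- params$n_cells_control
  n_e <- params$n_cells_exp
  group <- c(rep("control", n_c), rep("experimental", n_e))
  mu <- c(rep(params$control_mean, n_c),
          rep(params$control_mean * params$effect_ratio, n_e))
  sd <- c(rep(params$control_sd, n_c),
          rep(params$control_sd * params$effect_ratio, n_e))
  gray <- rnorm_truncated0(n_c + n_e, mu, sd)
  p1 <- stats::runif(n_c + n_e) < params$p1_fraction
  l1 <- stats::runif(n_c + n_e) < params$l1_fraction
  edu_rate <- ifelse(group == "control", params$edu_rate_control, params$edu_rate_exp)
  edu <- p1 & (stats::runif(n_c + n_e) < edu_rate)
  tibble::tibble(
    cell_id = sprintf("cell_%04d", seq_len(n_c + n_e)),
    group = group,
    gray_value = gray,
    p1 = p1,
    l1 = l1,
    edu = edu
  )
}

# Normal truncated below at 0 by rejection; cheap because gray-value means
# sit many SDs above zero in practice.
rnorm_truncated0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection failed to converge", call. = FALSE)
  }
  x
}
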