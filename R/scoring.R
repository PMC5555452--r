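#' Snap a raw size fraction onto the quarter-segment grid
#'
#' Tumors are scored as quarters of adult abdominal segments: a tumor
#' covering one quarter of a segment scores 0.25, half a segment 0.5, a full
#' segment 1.0, and so forth. A raw fraction is rounded to the nearest grid
#' value `0.25k` (`k >= 1`), ties rounding up, and any visible tumor scores
#' at least 0.25 — the grid has no zero for a tumor that exists.
#'
#' @param raw_fraction Numeric vector of positive size fractions (fraction of
#'   one abdominal segment covered; may exceed 1 for tumors spanning more
#'   than a segment).
#' @return Numeric vector on the grid \{0.25, 0.5, 0.75, ...\}.
#' @export
#' @examples
#' quantize_size(c(0.25, 0.5, 1.0))  # the printed scoring examples
#' quantize_size(0.05)               # visible but tiny -> 0.25
#' quantize_size(0.375)              # tie -> rounds up to 0.5
quantize_size <- function(raw_fraction) {
  if (any(!is.finite(raw_fraction)) || any(raw_fraction <= 0))
    stop("invalid measurement: size fractions must be positive and finite", call. = FALSE)
  # round half up to the nearest multiple of 0.25, floored at 0.25
  pmax(0.25, floor(raw_fraction / 0.25 + 0.5) * 0.25)
}

#' Per-animal Tumor Index
#'
#' The Tumor Index (TI) of an animal is the sum of all its tumor sizes in
#' quarter-segment units; a tumor-free animal has TI 0. Sizes must lie on the
#' quarter grid (use [quantize_size()] for raw fractions).
#'
#' @param tumor_sizes Numeric vector of sizes for one animal, or a list of
#'   such vectors (one element per animal, as in the `tumor_sizes`
#'   list-column of a screen dataset).
#' @return Numeric TI, one value per animal.
#' @export
#' @examples
#' tumor_index(numeric(0))      # tumor-free animal: 0
#' tumor_index(c(0.25, 0.5))    # 0.75
#' tumor_index(list(1.0, c(0.25, 0.25)))
tumor_index <- function(tumor_sizes) {
  if (!is.list(tumor_sizes)) tumor_sizes <- list(tumor_sizes)
  vapply(tumor_sizes, function(s) {
    if (length(s) == 0) return(0)
    if (any(!is.finite(s)) || any(s <= 0) ||
        any(abs(s / 0.25 - round(s / 0.25)) > 1e-9))
      stop("malformed record: tumor sizes must be positive multiples of 0.25",
           call. = FALSE)
    sum(s)
  }, numeric(1))
}

#' Summary statistics of a batch's control cross
#'
#' The normalization reference for a batch is the control outcross set up in
#' parallel: its mean TI and the sample SD (n - 1 denominator) of its TIs.
#' A batch whose control has fewer than two animals or zero SD cannot
#' normalize anything and is flagged degenerate.
#'
#' @param control_tis Numeric vector of TIs of the batch's control animals.
#' @param batch_id Identifier carried into the result.
#' @return A one-row tibble of class `control_stats`: `batch_id`, `n`,
#'   `mean_ti`, `sd_ti`.
#' @export
control_stats <- function(control_tis, batch_id = "b1") {
  if (length(control_tis) < 2)
    stop("degenerate batch ", batch_id, ": fewer than 2 control animals", call. = FALSE)
  s <- stats::sd(control_tis)
  if (s == 0)
    stop("degenerate batch ", batch_id, ": control TIs are all identical (SD = 0)",
         call. = FALSE)
  out <- tibble::tibble(
    batch_id = batch_id,
    n = length(control_tis),
    mean_ti = mean(control_tis),
    sd_ti = s
  )
  class(out) <- c("control_stats", class(out))
  out
}

#' Normalize a TI against its batch control
#'
#' The normalized tumor index is the per-animal z-score against the paired
#' control cross: `NTI = (TI - mean(control TI)) / SD(control TI)`. The
#' control mean itself maps to 0.
#'
#' @param ti Numeric vector of TIs.
#' @param stats A [control_stats()] row (or anything with `mean_ti` and
#'   `sd_ti`).
#' @return Numeric NTI vector, dimensionless (control-SD units).
#' @export
normalize_ti <- function(ti, stats) {
  if (!all(c("mean_ti", "sd_ti") %in% names(stats)))
    stop("stats must contain mean_ti and sd_ti", call. = FALSE)
  if (!is.finite(stats$sd_ti) || stats$sd_ti <= 0)
    stop("degenerate control stats: sd_ti must be > 0", call. = FALSE)
  (ti - stats$mean_ti) / stats$sd_ti
}

#' Score a screen dataset: per-animal TI and NTI
#'
#' Adds `ti` to every animal and `nti` computed against the animal's own
#' batch control (controls are never pooled across batches). Batches whose
#' control is degenerate (missing, < 2 animals, or zero TI spread) get
#' `NA` NTIs and are listed in the `degenerate_batches` attribute rather
#' than dropped silently.
#'
#' @param dataset A `screen_dataset` from [simulate_screen()], or a
#'   per-animal tibble with columns `animal_id`, `genotype_id`, `batch_id`,
#'   `role`, `tumor_sizes`.
#' @return The per-animal tibble with added columns `ti` and `nti`;
#'   attribute `control_stats` (per-batch tibble) and `degenerate_batches`
#'   (character vector).
#' @export
score_screen <- function(dataset) {
  animals <- if (inherits(dataset, "screen_dataset")) dataset$animals else dataset
  need <- c("animal_id", "genotype_id", "batch_id", "role", "tumor_sizes")
  if (!all(need %in% names(animals)))
    stop("animals table must have columns: ", paste(need, collapse = ", "), call. = FALSE)

  animals$ti <- tumor_index(animals$tumor_sizes)

  batches <- unique(animals$batch_id)
  stats_list <- list()
  degenerate <- character(0)
  animals$nti <- NA_real_
  for (b in batches) {
    in_batch <- animals$batch_id == b
    ctl_ti <- animals$ti[in_batch & animals$role == "control"]
    st <- tryCatch(control_stats(ctl_ti, batch_id = b), error = function(e) e)
    if (inherits(st, "error")) {
      degenerate <- c(degenerate, b)
      warning("batch ", b, " is unusable: ", conditionMessage(st), call. = FALSE)
      next
    }
    stats_list[[b]] <- st
    animals$nti[in_batch] <- normalize_ti(animals$ti[in_batch], st)
  }
  attr(animals, "control_stats") <- dplyr::bind_rows(stats_list)
  attr(animals, "degenerate_batches") <- degenerate
  animals
}
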