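#' Summarize one genotype's NTIs
#'
#' The genotype-level statistic is the mean of its animals' NTIs, plotted
#' with a standard error (sample SD of per-animal NTIs over `sqrt(n)`). A
#' cross that yielded no adult progeny is synthetic-lethal and short-circuits
#' the summary.
#'
#' @param ntis Numeric vector of per-animal NTIs for the genotype.
#' @param n_progeny Number of adult progeny recovered; 0 marks synthetic
#'   lethality.
#' @param genotype_id Identifier carried into the result.
#' @param threshold Classification threshold in control-SD units (see
#'   [classify()]).
#' @param min_n Minimum intended sample size; genotypes below it are still
#'   classified but flagged `low_n`.
#' @return A one-row tibble: `genotype_id`, `n`, `mean_nti`, `se_nti`,
#'   `classification`, `low_n`.
#' @export
summarize_genotype <- function(ntis, n_progeny, genotype_id = "g1",
                               threshold = 1, min_n = 15) {
  if (n_progeny == 0) {
    return(tibble::tibble(
      genotype_id = genotype_id, n = 0L,
      mean_nti = NA_real_, se_nti = NA_real_,
      classification = "synthetic_lethal", low_n = FALSE
    ))
  }
  if (length(ntis) == 0)
    stop("inconsistent input: n_progeny > 0 but no NTIs for ", genotype_id, call. = FALSE)
  if (anyNA(ntis)) {
    # animals from an unusable batch: cannot be classified
    return(tibble::tibble(
      genotype_id = genotype_id, n = length(ntis),
      mean_nti = NA_real_, se_nti = NA_real_,
      classification = "unusable", low_n = length(ntis) < min_n
    ))
  }
  m <- mean(ntis)
  se <- if (length(ntis) > 1) stats::sd(ntis) / sqrt(length(ntis)) else 0
  tibble::tibble(
    genotype_id = genotype_id,
    n = length(ntis),
    mean_nti = m,
    se_nti = se,
    classification = classify_mean_nti(m, threshold),
    low_n = length(ntis) < min_n
  )
}

#' Classify a genotype by its mean NTI
#'
#' A genotype is an enhancer if its mean NTI lies strictly more than
#' `threshold` control-SDs above the control (which sits at 0 by
#' construction), a suppressor if strictly more than `threshold` below, and
#' otherwise has no effect. Boundary values (mean NTI exactly at the
#' threshold) are not called: the rule is strict.
#'
#' @param summary A one-row genotype summary (from [summarize_genotype()]),
#'   or a numeric mean NTI.
#' @param threshold Positive threshold in control-SD units; default 1.
#' @return Classification label: `"enhancer"`, `"suppressor"`, `"no_effect"`,
#'   or the summary's existing label for synthetic-lethal/unusable rows.
#' @export
#' @examples
#' classify(1.2)   # enhancer
#' classify(1.0)   # exactly at the boundary: no_effect
#' classify(-1.2)  # suppressor
classify <- function(summary, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (is.numeric(summary)) return(classify_mean_nti(summary, threshold))
  if (summary$classification %in% c("synthetic_lethal", "unusable"))
    return(summary$classification)
  classify_mean_nti(summary$mean_nti, threshold)
}

classify_mean_nti <- function(mean_nti, threshold) {
  vapply(mean_nti, function(m) {
    if (is.na(m)) "unusable"
    else if (m > threshold) "enhancer"
    else if (m < -threshold) "suppressor"
    else "no_effect"
  }, character(1))
}

#' Analyze a screen: per-genotype summaries and classifications
#'
#' Scores every animal (TI, batch-paired NTI), aggregates per genotype, and
#' applies the strict `|mean NTI| > threshold` rule. Each genotype is
#' normalized against its own batch's control; control crosses themselves are
#' not classified. Genotypes in a degenerate batch are reported `unusable`,
#' and synthetic-lethal crosses `synthetic_lethal`, so every Df genotype
#' appears in the output exactly once.
#'
#' @param dataset A `screen_dataset` (from [simulate_screen()] or
#'   [read_screen_tsv()]), or a list with `animals` and `crosses` tibbles.
#' @param threshold Classification threshold in control-SD units.
#' @param min_n Minimum intended sample size for the `low_n` flag.
#' @return A tibble of genotype summaries sorted by `mean_nti` (NA last),
#'   with attribute `degenerate_batches`.
#' @export
analyze_screen <- function(dataset, threshold = 1, min_n = 15) {
  scored <- score_screen(dataset)
  crosses <- if (!is.null(dataset$crosses)) dataset$crosses else NULL

  df_animals <- scored[scored$role == "df", , drop = FALSE]
  summaries <- lapply(split(df_animals, df_animals$genotype_id), function(g) {
    summarize_genotype(g$nti, n_progeny = nrow(g), genotype_id = g$genotype_id[1],
                       threshold = threshold, min_n = min_n)
  })

  # crosses with zero progeny never appear in the animals table
  if (!is.null(crosses)) {
    missing <- crosses[crosses$role == "df" &
                         !(crosses$genotype_id %in% df_animals$genotype_id), ,
                       drop = FALSE]
    for (i in seq_len(nrow(missing))) {
      g <- missing$genotype_id[i]
      if (missing$n_progeny[i] == 0) {
        summaries[[g]] <- summarize_genotype(numeric(0), n_progeny = 0,
                                             genotype_id = g,
                                             threshold = threshold, min_n = min_n)
      }
    }
  }

  out <- dplyr::bind_rows(summaries)
  out <- out[order(out$mean_nti, na.last = TRUE), , drop = FALSE]
  attr(out, "degenerate_batches") <- attr(scored, "degenerate_batches")
  out
}

#' Tally classifications
#'
#' @param summaries Output of [analyze_screen()].
#' @return A tibble with one row per classification label and its count; all
#'   five possible labels are present (zero counts included) so the tallies
#'   always sum to the number of genotypes.
#' @export
classification_counts <- function(summaries) {
  labels <- c("enhancer", "suppressor", "no_effect", "synthetic_lethal", "unusable")
  counts <- vapply(labels, function(l) sum(summaries$classification == l), integer(1))
  tibble::tibble(classification = labels, count = counts)
}
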