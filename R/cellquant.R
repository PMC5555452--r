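#' Control-normalized intensity comparison for a mixed-cell table
#'
#' Per-cell mean gray values from a mixed-cell slide are divided by the mean
#' of the reference (control) group, so the control mean is exactly 1 and the
#' experimental mean is a ratio to control. Significance is assessed with a
#' two-sided pooled-variance Student's t test (see [compare_groups()]),
#' which is invariant to the common rescaling.
#'
#' @param cells A per-cell tibble with at least `group` (`"control"` /
#'   `"experimental"`) and `gray_value` columns, e.g. from
#'   [simulate_cell_table()] or [read_cells_tsv()].
#' @param var_equal Use the pooled-variance Student's t (`TRUE`, default);
#'   `FALSE` gives Welch's unequal-variance test.
#' @return A one-row tibble of class `quant_comparison`: `n_control`,
#'   `n_exp`, `normalized_control_mean` (identically 1),
#'   `normalized_exp_mean`, `t_statistic`, `df`, `p_value`.
#' @export
normalize_intensities <- function(cells, var_equal = TRUE) {
  if (!all(c("group", "gray_value") %in% names(cells)))
    stop("cells table must have 'group' and 'gray_value' columns", call. = FALSE)
  ctl <- cells$gray_value[cells$group == "control"]
  exp_ <- cells$gray_value[cells$group == "experimental"]
  if (length(ctl) < 2 || length(exp_) < 2)
    stop("need >= 2 cells in each of the control and experimental groups", call. = FALSE)
  m_ctl <- mean(ctl)
  if (m_ctl <= 0) stop("control group mean must be > 0 to normalize", call. = FALSE)
  tst <- compare_groups(exp_ / m_ctl, ctl / m_ctl, var_equal = var_equal)
  out <- tibble::tibble(
    n_control = length(ctl),
    n_exp = length(exp_),
    normalized_control_mean = 1,
    normalized_exp_mean = mean(exp_) / m_ctl,
    t_statistic = tst$t_statistic,
    df = tst$df,
    p_value = tst$p_value
  )
  class(out) <- c("quant_comparison", class(out))
  out
}

#' Two-sample Student's t test
#'
#' Two-sided, pooled-variance (equal-variance) Student's t by default, as is
#' conventional when comparing per-cell intensities between two genotypes on
#' one slide; Welch's correction is available behind `var_equal = FALSE`.
#' The degenerate case of zero pooled variance is handled explicitly rather
#' than erroring: identical group means give `t = 0, p = 1`; different means
#' with zero within-group variance give an infinite `t` and a p value
#' reported as the smallest representable positive double (an upper bound,
#' in the spirit of "P < ..." reporting).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student's t if `TRUE` (default), Welch
#'   otherwise.
#' @return A list with `t_statistic`, `df`, `p_value` (two-sided).
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient data: each group needs >= 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t_statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
    return(list(
      t_statistic = sign(mean(a) - mean(b)) * Inf,
      df = length(a) + length(b) - 2,
      p_value = .Machine$double.xmin  # upper bound on an unrepresentably small p
    ))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' EdU-positive fraction of P1-positive cells, per group
#'
#' The proliferating-plasmatocyte fraction: among P1-positive cells (the
#' plasmatocyte marker), the fraction also positive for the S-phase label
#' EdU. P1-negative cells are ignored entirely; a group with no P1-positive
#' cells has an undefined fraction (`NA`), never 0.
#'
#' @param cells A per-cell tibble with `group`, and logical `p1` and `edu`
#'   columns.
#' @return A tibble with one row per group: `group`, `n_p1`, `n_p1_edu`,
#'   `fraction`.
#' @export
edu_fraction <- function(cells) {
  if (nrow(cells) == 0)
    stop("invalid table: no cells", call. = FALSE)
  if (!all(c("group", "p1", "edu") %in% names(cells)))
    stop("cells table must have 'group', 'p1', 'edu' columns", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(cells, .data$group),
    n_p1 = sum(.data$p1),
    n_p1_edu = sum(.data$p1 & .data$edu),
    fraction = ifelse(.data$n_p1 > 0, .data$n_p1_edu / .data$n_p1, NA_real_),
    .groups = "drop"
  )
}
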