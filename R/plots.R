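#' Bar plot of genotype mean NTI with SE bars
#'
#' Mimics the standard presentation of a modifier screen: one bar per
#' genotype, mean NTI on the y axis with standard-error bars, the control at
#' 0 and dashed lines at the classification thresholds. Suppressors and
#' enhancers are colored by call.
#'
#' @param summaries Output of [analyze_screen()].
#' @param threshold Threshold lines to draw (control-SD units).
#' @param hits_only Drop `no_effect` genotypes before plotting (default
#'   `TRUE`, as a full kit screen has hundreds of bars).
#' @return A ggplot object.
#' @export
plot_nti <- function(summaries, threshold = 1, hits_only = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_nti requires the ggplot2 package", call. = FALSE)
  d <- summaries[!is.na(summaries$mean_nti), , drop = FALSE]
  if (hits_only) d <- d[d$classification %in% c("enhancer", "suppressor"), , drop = FALSE]
  d <- d[order(d$mean_nti), , drop = FALSE]
  d$genotype_id <- factor(d$genotype_id, levels = d$genotype_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype_id, y = .data$mean_nti,
                                  fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_nti - .data$se_nti,
                                        ymax = .data$mean_nti + .data$se_nti),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = c(-threshold, 0, threshold),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::scale_fill_manual(values = c(enhancer = "#2e7d32",
                                          suppressor = "#6a1b9a",
                                          no_effect = "grey70")) +
    ggplot2::labs(x = NULL, y = "mean NTI (control-SD units)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Power curve of the classification rule
#'
#' @param oc An `operating_characteristics` object from [power_curve()].
#' @return A ggplot object.
#' @export
plot_power <- function(oc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_power requires the ggplot2 package", call. = FALSE)
  d <- oc$power_by_effect
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = .data$power)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "effect multiplier (tumor-count rate)",
                  y = "detection probability") +
    ggplot2::theme_classic()
}
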