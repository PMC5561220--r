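#' Funnel plot of per-SNP Wald ratios
#'
#' Plots each SNP's Wald ratio against its precision (1/SE). Vertical
#' reference lines mark the supplied method estimates. Asymmetry of the
#' funnel suggests directional pleiotropy.
#'
#' @param h An `mr_harmonized` tibble.
#' @param estimates Optional estimate tibble from [mr_estimates()] for
#'   reference lines.
#' @return A ggplot object.
#' @export
plot_funnel <- function(h, estimates = NULL) {
  fd <- funnel_data(h)
  p <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$ratio,
                                        y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Wald ratio (causal estimate per SNP)",
                  y = "Precision (1 / SE)") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    est <- estimates[!is.na(estimates$estimate), ]
    p <- p + ggplot2::geom_vline(
      data = est,
      ggplot2::aes(xintercept = .data$estimate, colour = .data$method),
      linetype = "dashed") +
      ggplot2::labs(colour = "Method")
  }
  p
}

#' Scatter plot of SNP-outcome against SNP-exposure effects
#'
#' Per-SNP effects with 95% error bars on the outcome axis and one fitted
#' line per method (through the origin for IVW and the weighted median;
#' free intercept for MR-Egger).
#'
#' @param h An `mr_harmonized` tibble.
#' @param estimates Estimate tibble from [mr_estimates()] computed on the
#'   same set.
#' @return A ggplot object.
#' @export
plot_scatter <- function(h, estimates) {
  sd_ <- scatter_data(h, estimates)
  lines <- attr(sd_, "lines")
  ggplot2::ggplot(sd_, ggplot2::aes(x = .data$beta_exposure,
                                    y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$outcome_low,
                                        ymax = .data$outcome_high),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome", colour = "Method") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of an MR report
#'
#' Estimates with 95% confidence intervals per method, faceted by
#' exposure/outcome, coloured by analysis variant (all SNPs vs excluding
#' flagged SNPs). NA (infeasible) rows are omitted from the plot.
#'
#' @param object An `mr_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_report
#' @export
autoplot.mr_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$estimate), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$method,
                                   colour = .data$variant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::facet_grid(outcome ~ exposure) +
    ggplot2::labs(x = "Causal estimate (95% CI)", y = NULL,
                  colour = "Variant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
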