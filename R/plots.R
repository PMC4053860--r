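# ggplot2 views of the main result types.

#' Plot a binned bootstrap series
#'
#' Mean response per methylation-difference bin with the percentile
#' bootstrap interval (bins too small for an interval are drawn as points
#' only).
#'
#' @param object An `iidmr_binned` tibble from [binned_mean_ci()] or
#'   [expression_ratio_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.iidmr_binned <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin_mid, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "methylation difference (beta)",
                  y = "mean response (95% bootstrap CI)") +
    ggplot2::theme_minimal()
}

#' Plot category enrichment fractions
#'
#' Per-category iiDMR fraction with its binomial interval; the dashed line
#' is the overall (background) iiDMR fraction.
#'
#' @param object An `iidmr_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.iidmr_enrichment <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue", na.rm = TRUE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = attr(object, "background_fraction"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "iiDMR probe fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Scatter plot of intra- versus inter-pair RMS variability
#'
#' @param profile A tibble from [rms_profile()].
#' @param alpha Point alpha.
#' @return A ggplot object.
#' @export
plot_rms_profile <- function(profile, alpha = 0.3) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$rms_intra,
                                        y = .data$rms_inter)) +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::labs(x = "intra-pair RMS difference",
                  y = "inter-pair RMS difference (permuted pairs)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
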