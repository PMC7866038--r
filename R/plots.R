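#' Plot a concentration-time profile
#'
#' @param object An `etscc_profile` tibble.
#' @param ... Unused.
#' @return A ggplot of blood and peripheral 5-FU concentration vs time.
#' @exportS3Method ggplot2::autoplot
autoplot.etscc_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("sigma_B", "sigma_P"),
                              names_to = "compartment",
                              values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$concentration,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(
      labels = c(sigma_B = "blood", sigma_P = "peripheral")) +
    ggplot2::labs(x = "time (h)", y = "5-FU concentration (µg/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An `etscc_roc` object from [roc_curve()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.etscc_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(1 - .data$specificity,
                                       .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot per-class complementary cumulative distributions of eTSCC
#'
#' @param report An `etscc_report` from [classifier_report()], or a ccd
#'   tibble from [ccd()].
#' @param threshold Optional vertical threshold line; taken from the
#'   report when available.
#' @return A ggplot.
#' @export
plot_ccd <- function(report, threshold = NULL) {
  if (inherits(report, "etscc_report")) {
    if (is.null(threshold)) threshold <- report$threshold
    report <- report$ccd
  }
  p <- ggplot2::ggplot(report, ggplot2::aes(.data$x, .data$ccd,
                                            colour = .data$label)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "eTSCC (µg/mL)",
                  y = "fraction of patients above x", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
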