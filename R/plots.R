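#' Scatter plot of proxy versus in-situ UTCI
#'
#' @param pairs Paired samples with `utci_insitu` and `utci_proxy`.
#' @return A ggplot object with the identity line for reference.
#' @export
plot_agreement <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$utci_insitu,
                                      y = .data$utci_proxy)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "in-situ UTCI (degC)", y = "proxy UTCI (degC)") +
    ggplot2::theme_minimal()
}

#' Boxplots of proxy-minus-in-situ bias by stratum
#'
#' @param pairs Paired samples carrying a `bias` column (proxy minus in
#'   situ) or both UTCI columns.
#' @param by Name of the stratifying column (e.g. `season`, `morphology`,
#'   `stress_category`).
#' @return A ggplot object.
#' @export
plot_bias_boxplots <- function(pairs, by = "season") {
  if (!"bias" %in% names(pairs)) {
    pairs$bias <- pairs$utci_proxy - pairs$utci_insitu
  }
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data[[by]], y = .data$bias)) +
    ggplot2::geom_boxplot() +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "bias, proxy - in situ (degC UTCI)") +
    ggplot2::theme_minimal()
}
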