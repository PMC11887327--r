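#' Plot empirical rejection rates
#'
#' Power (or type-1 error, at `beta = 0`) against the effect multiplier, one
#' line per working correlation structure, with binomial error bars and the
#' nominal level as a dashed reference.
#'
#' @param rates Output of [rejection_rates()].
#' @param alpha Which significance level to display (default 0.05).
#' @return A ggplot object.
#' @export
plot_power <- function(rates, alpha = 0.05) {
  df <- rates[rates$alpha == alpha, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$beta),
                                   y = .data$rejection,
                                   colour = .data$wc, group = .data$wc)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$rejection - 2 * .data$se,
      ymax = .data$rejection + 2 * .data$se)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::labs(x = expression(beta), y = "rejection rate",
                  colour = "working\ncorrelation") +
    ggplot2::theme_minimal()
}

#' Plot the compositional-bias experiment
#'
#' Mean bias of the pooled-node effect estimate (with interquartile band)
#' against the external-taxon inflation multiplier, one line per reference
#' mode.
#'
#' @param bias Output of [bias_summary()].
#' @return A ggplot object.
#' @export
plot_bias <- function(bias) {
  ggplot2::ggplot(bias, ggplot2::aes(x = factor(.data$multiplier),
                                     y = .data$mean_bias,
                                     colour = .data$denominator,
                                     group = .data$denominator)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_bias - .data$iqr_bias / 2,
      ymax = .data$mean_bias + .data$iqr_bias / 2)) +
    ggplot2::labs(x = "external-taxon inflation (SD multiples)",
                  y = "bias of " ~ hat(beta)[0], colour = "reference") +
    ggplot2::theme_minimal()
}
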