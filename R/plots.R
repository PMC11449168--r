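## Simple diagnostic graphics: caterpillar plots of realized individual
## effects and a random-effect correlation panel.

#' Caterpillar plot of per-individual estimates
#'
#' @param realized data frame from [realized_phenotypes()] or
#'   [realized_riiv()].
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_caterpillar <- function(realized, ylab = "realized value") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- realized[order(realized$mean), ]
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$hpd_low,
                                        ymax = .data$hpd_high),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = mean(d$mean), linetype = "dashed") +
    ggplot2::labs(x = "individual (ranked)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Correlation summary plot
#'
#' Point estimates and 95% HPD intervals of the mean-rIIV correlations and
#' behavioural syndromes.
#'
#' @param correlations data frame from [random_effect_correlations()].
#' @return a ggplot object.
#' @export
plot_correlations <- function(correlations) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- correlations
  d$label <- paste(d$quantity, d$pair, sep = ": ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hpd_low,
                                         xmax = .data$hpd_high), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "among-individual correlation", y = NULL) +
    ggplot2::theme_minimal()
}
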