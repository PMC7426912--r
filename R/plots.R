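#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall curve
#'
#' Step plot of precision against recall with the average precision in the
#' subtitle, mirroring the usual presentation of panel validation results.
#'
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::bind_rows(tibble::tibble(threshold = Inf, recall = 0,
                                        precision = df$precision[1]), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", linewidth = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  subtitle = sprintf("Average precision = %.3f",
                                     curve_ap(object))) +
    ggplot2::theme_minimal()
}

#' Plot selection frequencies and their normal QQ view
#'
#' @param freq Frequency tibble from [selection_frequencies()].
#' @param c_star Optional threshold drawn as a horizontal line.
#' @return A ggplot object: gene selection counts in rank order.
#' @export
plot_selection_frequencies <- function(freq, c_star = NULL) {
  df <- freq[order(-freq$count), ]
  df$rank <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Gene (sorted by selection count)",
                  y = "Times selected") +
    ggplot2::theme_minimal()
  if (!is.null(c_star)) {
    p <- p + ggplot2::geom_hline(yintercept = c_star, linetype = "dashed")
  }
  p
}

#' Normal QQ plot of selection counts with the quartile reference line
#'
#' @inheritParams plot_selection_frequencies
#' @return A ggplot object.
#' @export
plot_frequency_qq <- function(freq, c_star = NULL) {
  counts <- sort(as.numeric(freq$count))
  df <- tibble::tibble(theoretical = qnorm(ppoints(length(counts))),
                       observed = counts)
  qs_obs <- quantile(counts, c(0.25, 0.75), names = FALSE)
  qs_the <- qnorm(c(0.25, 0.75))
  slope <- (qs_obs[2] - qs_obs[1]) / (qs_the[2] - qs_the[1])
  intercept <- qs_obs[1] - slope * qs_the[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theoretical, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = slope, intercept = intercept, colour = "grey40") +
    ggplot2::labs(x = "Standard normal quantile", y = "Selection count") +
    ggplot2::theme_minimal()
  if (!is.null(c_star)) {
    p <- p + ggplot2::geom_hline(yintercept = c_star, linetype = "dashed")
  }
  p
}
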