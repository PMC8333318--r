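# ggplot2 displays for metric curves, permutation results and hub tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot metric-versus-density curves
#'
#' One panel per graph statistic, group as colour — the conventional
#' display for density-swept network metrics.
#'
#' @param object A `metab_curves` tibble from [metric_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metab_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$density, y = .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "network density", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a permutation test across the density sweep
#'
#' Observed group difference per density with the permutation critical
#' value; densities where the difference is significant are shaded.
#'
#' @param object A `metab_permutation` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metab_permutation <- function(object, ...) {
  df <- tidy(object)
  key <- names(df)[1]
  sig <- df[df$significant, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$density)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed),
                       colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$critical),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data[[key]]), scales = "free_y") +
    ggplot2::labs(x = "network density",
                  y = "group difference (patient - control)") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_point(data = sig,
                                 ggplot2::aes(y = .data$observed),
                                 colour = "firebrick", size = 1.6)
  }
  p
}

#' Plot a hub table
#'
#' Normalized betweenness per region with the hub threshold marked.
#'
#' @param hubs A hub table from [classify_hubs()].
#' @return A ggplot object.
#' @export
plot_hubs <- function(hubs) {
  thr <- attr(hubs, "threshold") %||% 1.5
  df <- hubs[order(-hubs$b), , drop = FALSE]
  df$region <- factor(df$region, levels = rev(df$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$region,
                                   fill = .data$hub)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "normalized betweenness b_i", y = NULL,
                  fill = paste0("b_i > ", thr)) +
    ggplot2::theme_minimal()
}
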