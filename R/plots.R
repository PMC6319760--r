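#' Plot Q time series
#'
#' One line per replica, faceted by selection when several are present.
#'
#' @param series Tidy Q tibble from [q_series()] or friends.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_q_series <- function(series, alpha = 0.6) {
  p <- ggplot2::ggplot(series, ggplot2::aes(
    x = .data$time_ns, y = .data$q,
    group = .data$replica_id, colour = factor(.data$replica_id))) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (ns)", y = "Q", colour = "replica") +
    ggplot2::theme_minimal()
  if (length(unique(series$selection)) > 1) {
    p <- p + ggplot2::facet_wrap(~selection)
  }
  p
}

#' Plot per-residue final-window Q means
#'
#' Replica means per residue with the unstable-residue threshold drawn as a
#' horizontal line; the standard view for spotting unfolding residues.
#'
#' @param window_means Tibble from [final_window_means()] with
#'   `residue_index`, `replica_id`, `mean_q`.
#' @param q_threshold Threshold line (default 0.6).
#' @return A ggplot object.
#' @export
plot_per_residue_q <- function(window_means, q_threshold = 0.6) {
  ggplot2::ggplot(window_means, ggplot2::aes(
    x = .data$residue_index, y = .data$mean_q)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = q_threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "residue index", y = "final-window mean Q") +
    ggplot2::theme_minimal()
}

#' Plot per-system Q against melting temperature
#'
#' @param summaries Tibble with `system_id`, `selection`, `mean` (see
#'   [tidy.stability_report()]).
#' @param tm Tibble with `system_id`, `tm_celsius`.
#' @param selection Which Q selection to plot (default `"all-all"`).
#' @return A ggplot object.
#' @export
plot_q_vs_tm <- function(summaries, tm, selection = "all-all") {
  d <- dplyr::inner_join(summaries[summaries$selection == selection, ],
                         tm, by = "system_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tm_celsius, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$system_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Tm (deg C)", y = paste0("final-window Q (",
                                               selection, ")")) +
    ggplot2::theme_minimal()
}

#' Autoplot a stability report
#'
#' Per-residue final-window mean Q with the detection threshold; the
#' quickest visual check of which residues drive instability.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  plot_per_residue_q(object$per_residue_means,
                     q_threshold = object$params$q_threshold) +
    ggplot2::ggtitle(object$system_id)
}
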