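run_long <- function(run, value_fun) {
  out <- lapply(run$curves, value_fun)
  do.call(rbind, lapply(names(out), function(id) {
    tibble::tibble(sample_id = id,
                   temperature_c = run$curves[[id]]$temperatures_c,
                   value = out[[id]])
  }))
}

#' Diagnostic plots: raw melts, derivative peaks, normalized curves
#'
#' `plot_melt_curves` overlays the raw fluorescence traces;
#' `plot_derivative` the smoothed -dF/dT traces with the panel Tms marked;
#' `plot_normalized` the two-window normalized curves for one stage, with the
#' normalization windows shaded. The control curve is drawn heavier.
#'
#' @param run A [melt_run()].
#' @param panel An [amplicon_panel()].
#' @param stage Stage (1 or 2) for the normalized plot.
#' @param windows Optional manual [normalization_windows()].
#' @return A ggplot object.
#' @export
plot_melt_curves <- function(run) {
  df <- run_long(run, function(cv) cv$fluorescence)
  df$is_control <- df$sample_id == run$control_sample_id
  ggplot2::ggplot(df, ggplot2::aes(.data$temperature_c, .data$value,
                                   group = .data$sample_id,
                                   linewidth = .data$is_control)) +
    ggplot2::geom_line(alpha = 0.6, colour = "steelblue4") +
    ggplot2::scale_linewidth_manual(values = c(0.3, 1.0), guide = "none") +
    ggplot2::labs(x = "Temperature (°C)", y = "Fluorescence",
                  title = "Raw melt curves") +
    ggplot2::theme_minimal()
}

#' @rdname plot_melt_curves
#' @export
plot_derivative <- function(run, panel) {
  df <- run_long(run, function(cv) {
    negative_derivative(smooth_curve(cv))$minus_dfdt
  })
  df$is_control <- df$sample_id == run$control_sample_id
  tms <- panel$amplicons
  ggplot2::ggplot(df, ggplot2::aes(.data$temperature_c, .data$value,
                                   group = .data$sample_id,
                                   linewidth = .data$is_control)) +
    ggplot2::geom_line(alpha = 0.6, colour = "firebrick4") +
    ggplot2::geom_vline(xintercept = tms$tm_c, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::annotate("text", x = tms$tm_c, y = Inf, label = tms$gene,
                      vjust = 1.5, size = 3) +
    ggplot2::scale_linewidth_manual(values = c(0.3, 1.0), guide = "none") +
    ggplot2::labs(x = "Temperature (°C)", y = "-dF/dT",
                  title = "Melt peak plot") +
    ggplot2::theme_minimal()
}

#' @rdname plot_melt_curves
#' @export
plot_normalized <- function(run, panel, stage = 1L, windows = NULL) {
  if (is.null(windows)) windows <- place_windows(run, panel, stage = stage)
  df <- run_long(run, function(cv) {
    normalize_between(cv, windows)$normalized
  })
  df$is_control <- df$sample_id == run$control_sample_id
  shade <- data.frame(xmin = c(windows$pre[1L], windows$post[1L]),
                      xmax = c(windows$pre[2L], windows$post[2L]))
  ggplot2::ggplot(df, ggplot2::aes(.data$temperature_c, .data$value)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "grey80", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id,
                                    linewidth = .data$is_control),
                       alpha = 0.6, colour = "darkgreen") +
    ggplot2::scale_linewidth_manual(values = c(0.3, 1.0), guide = "none") +
    ggplot2::labs(x = "Temperature (°C)", y = "Normalized fluorescence (%)",
                  title = sprintf("Stage-%d normalized curves", stage)) +
    ggplot2::theme_minimal()
}
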