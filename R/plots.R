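#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_col
#'   facet_wrap labs theme_minimal scale_color_viridis_d vars
NULL

#' Plot a QCM-D trace
#'
#' Frequency and dissipation shifts versus time, one line per harmonic, with
#' dashed vertical lines at the flow markers when available.
#'
#' @param object A [qcmd_trace()].
#' @param markers Optional [flow_markers()]; defaults to markers stored in
#'   the trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qcmd_trace
#' @export
autoplot.qcmd_trace <- function(object, markers = trace_markers(object), ...) {
  long <- object |>
    tidyr::pivot_longer(c("delta_f", "delta_D"),
                        names_to = "signal", values_to = "value") |>
    mutate(signal = factor(.data$signal, levels = c("delta_f", "delta_D"),
                           labels = c("Δf (Hz)", "ΔD (1e-6)")))
  p <- ggplot(long, aes(x = .data$time_min, y = .data$value,
                        color = factor(.data$harmonic))) +
    geom_line() +
    facet_wrap(vars(.data$signal), ncol = 1, scales = "free_y") +
    labs(x = "time (min)", y = NULL, color = "harmonic") +
    theme_minimal()
  if (!is.null(markers)) {
    at <- c(markers$t_start, markers$t_rinse)
    p <- p + geom_vline(xintercept = at, linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Dissipation-versus-frequency phase plot
#'
#' The diagnostic plot for reading deposition mechanisms: the frequency axis
#' is reversed so that travel to the right is mass gain and travel upward is
#' increasing viscoelasticity (adsorption runs north-east, rupture
#' south-west, direct bilayer deposition east).
#'
#' @param trace A [qcmd_trace()].
#' @param harmonic Harmonic to plot.
#' @param smooth_window Moving-average width, samples.
#' @return A ggplot object.
#' @export
plot_phase_trajectory <- function(trace, harmonic = 3L, smooth_window = 5L) {
  s <- harmonic_series(trace, harmonic)
  df <- tibble(delta_f = moving_average(s$delta_f, smooth_window),
               delta_D = moving_average(s$delta_D, smooth_window),
               time_min = s$time_min)
  ggplot(df, aes(x = -.data$delta_f, y = .data$delta_D,
                 color = .data$time_min)) +
    ggplot2::geom_path() +
    labs(x = "-Δf (Hz)  → mass gain",
         y = "ΔD (1e-6)  → viscoelasticity",
         color = "time (min)") +
    theme_minimal()
}

#' Plot a size distribution
#'
#' @param object A [size_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$d_nm, y = .data$value)) +
    geom_col(width = 0.04 * object$d_nm, fill = "steelblue") +
    ggplot2::scale_x_log10() +
    labs(x = "diameter (nm)",
         y = paste0("% ", dist_basis(object)),
         title = if (is.finite(dist_timestamp(object) %||% NA)) {
           paste0("day ", dist_timestamp(object))
         } else {
           NULL
         }) +
    theme_minimal()
}
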