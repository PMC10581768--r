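#' Plot simulated waveforms
#'
#' Faceted line plot of selected signals against time.
#'
#' @param object A `cvr_sim`.
#' @param signals Character vector of columns to plot.
#' @param t_range Optional length-2 numeric window, s.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cvr_sim
#' @export
autoplot.cvr_sim <- function(object,
                             signals = c("P_lv", "P_ao", "V_lv", "V_rv"),
                             t_range = NULL, ...) {
  long <- tidy.cvr_sim(object, signals = signals)
  if (!is.null(t_range)) {
    long <- long[long$t >= t_range[1] & long$t <= t_range[2], ]
  }
  long$signal <- factor(long$signal, levels = signals)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ventricular pressure-volume loop
#'
#' @param sim A `cvr_sim`.
#' @param ventricle `"lv"` or `"rv"`.
#' @param t_range Optional length-2 numeric window, s (e.g. a settled
#'   couple of beats).
#' @return A ggplot object.
#' @export
plot_pv_loop <- function(sim, ventricle = c("lv", "rv"), t_range = NULL) {
  ventricle <- match.arg(ventricle)
  ts <- sim$timeseries
  if (!is.null(t_range)) ts <- ts[ts$t >= t_range[1] & ts$t <= t_range[2], ]
  v <- ts[[paste0("V_", ventricle)]] * 1000  # ml for plotting
  p <- ts[[paste0("P_", ventricle)]]
  ggplot2::ggplot(data.frame(v = v, p = p),
                  ggplot2::aes(x = .data$v, y = .data$p)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::labs(x = sprintf("%s volume (ml)", toupper(ventricle)),
                  y = sprintf("%s pressure (mmHg)", toupper(ventricle))) +
    ggplot2::theme_minimal()
}
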