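#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into long format
#'
#' @param x A `cvr_sim`.
#' @param signals Optional character vector of column names to keep
#'   (defaults to all state and derived signals).
#' @param ... Unused.
#' @return A tibble with columns `t`, `signal`, `value`.
#' @method tidy cvr_sim
#' @export
tidy.cvr_sim <- function(x, signals = NULL, ...) {
  ts <- x$timeseries
  if (!is.null(signals)) ts <- ts[c("t", intersect(signals, names(ts)))]
  tidyr::pivot_longer(ts, -"t", names_to = "signal", values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x A `cvr_sim`.
#' @param ... Unused.
#' @return A one-row tibble: preset and mode flags, duration, sample
#'   count, solver diagnostics, volume-conservation error, minimum valve
#'   flow and septum-solver iteration statistics.
#' @method glance cvr_sim
#' @export
glance.cvr_sim <- function(x, ...) {
  tibble::tibble(
    preset = x$config$preset,
    valves = if (x$config$inertial) "inertial" else "noninertial",
    septum = x$config$septum,
    respiration = x$config$respiration,
    hr_mode = if (x$config$variable_hr) "variable" else "constant",
    t_end = x$config$t_end,
    n_samples = nrow(x$timeseries),
    steps_accepted = x$meta$steps_accepted,
    fevals = x$meta$fevals,
    conservation_error = x$meta$conservation_error,
    min_valve_flow = x$meta$min_valve_flow,
    newton_max_iter = x$meta$newton$max_iterations,
    newton_mean_iter = x$meta$newton$total_iterations /
      max(x$meta$newton$evals, 1L)
  )
}
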