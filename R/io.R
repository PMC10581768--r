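#' Write and read simulation time series
#'
#' Delimited text (CSV), one row per grid sample, columns in documented
#' order: `t`, the state trajectories, then the derived signals. Doubles
#' round-trip bit-exactly.
#'
#' @param sim A `cvr_sim`, or a data frame of samples.
#' @param path File path.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a tibble.
#' @name timeseries-io
NULL

#' @rdname timeseries-io
#' @export
write_timeseries <- function(sim, path) {
  df <- if (inherits(sim, "cvr_sim")) sim$timeseries else sim
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}

#' @rdname timeseries-io
#' @export
read_timeseries <- function(path) {
  # base read.csv: strtod parsing is correctly rounded, so the shortest
  # round-trip representations written by write_csv come back bit-exactly
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric")
  tibble::as_tibble(df)
}

#' Write and read a structured metrics report
#'
#' A plain-text report with three sections: `[meta]` (run configuration
#' and solver diagnostics as `key=value` lines), `[beats]` and
#' `[breaths]` (CSV tables from [extract_beats()] and
#' [extract_breaths()]). Tables round-trip losslessly through
#' `read_metrics`.
#'
#' @param sim A `cvr_sim`.
#' @param path File path.
#' @param beats,breaths Optional precomputed metric tables; computed from
#'   `sim` when omitted (breaths only when a respiratory model is present).
#' @return `write_metrics` returns `path` invisibly; `read_metrics` returns
#'   a list with elements `meta` (named character), `beats`, `breaths`.
#' @name metrics-io
NULL

#' @rdname metrics-io
#' @export
write_metrics <- function(sim, path, beats = NULL, breaths = NULL) {
  if (is.null(beats)) beats <- extract_beats(sim)
  if (is.null(breaths)) {
    breaths <- if ("y" %in% names(sim$timeseries)) extract_breaths(sim)
  }
  cfg <- sim$config
  meta <- c(preset = cfg$preset,
            t_end = format(cfg$t_end, digits = 17),
            grid_dt = format(cfg$grid_dt, digits = 17),
            atol = format(cfg$atol, digits = 17),
            rtol = format(cfg$rtol, digits = 17),
            septum = cfg$septum,
            respiration = cfg$respiration,
            valves = if (cfg$inertial) "inertial" else "noninertial",
            hr_mode = if (cfg$variable_hr) "variable" else "constant",
            steps_accepted = format(sim$meta$steps_accepted),
            fevals = format(sim$meta$fevals),
            conservation_error = format(sim$meta$conservation_error,
                                        digits = 17),
            min_valve_flow = format(sim$meta$min_valve_flow, digits = 17))
  lines <- c("# cvrsim metrics v1", "[meta]",
             paste0(names(meta), "=", meta),
             "[beats]",
             readr::format_csv(beats))
  if (!is.null(breaths)) {
    lines <- c(lines, "[breaths]", readr::format_csv(breaths))
  }
  writeLines(sub("\n+$", "", lines), path)
  invisible(path)
}

#' @rdname metrics-io
#' @export
read_metrics <- function(path) {
  lines <- readLines(path)
  sec <- cumsum(grepl("^\\[(meta|beats|breaths)\\]$", lines))
  labs <- sub("^\\[|\\]$", "", lines[grepl("^\\[", lines)])
  labs <- gsub("\\[|\\]", "", labs)
  get_sec <- function(lab) {
    i <- which(labs == lab)
    if (!length(i)) return(NULL)
    body <- lines[sec == i]
    body[-1]
  }
  meta_lines <- get_sec("meta")
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = "="),
                                 ""),
                          vapply(kv, `[`, "", 1))
  parse_tab <- function(body) {
    if (is.null(body) || !length(body)) return(NULL)
    tibble::as_tibble(utils::read.csv(text = paste(body, collapse = "\n")))
  }
  list(meta = meta, beats = parse_tab(get_sec("beats")),
       breaths = parse_tab(get_sec("breaths")))
}
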