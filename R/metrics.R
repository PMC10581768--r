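#' Per-beat haemodynamic metrics
#'
#' Splits a simulation into cardiac cycles and summarises each: stroke
#' volumes (per-beat max minus min ventricular volume), systolic/diastolic
#' aortic pressure (per-beat max/min), and mean heart rate. In constant-HR
#' mode beats are delimited analytically at integer multiples of the
#' cardiac period; in variable-HR mode they are delimited by integer
#' crossings of the cardiac phase state, located by linear interpolation.
#' Only complete beats are reported. When a respiratory model is present,
#' each beat is flagged inspiratory if the alveolar airflow is positive at
#' the beat's start.
#'
#' @param sim A `cvr_sim` from [simulate_cvs()].
#' @return A tibble with one row per complete beat: `beat`, `t_start`,
#'   `t_end`, `SV_lv`, `SV_rv` (l), `P_ao_sys`, `P_ao_dia` (mmHg),
#'   `hr_mean` (min^-1) and, when available, `inspiration` (logical).
#' @export
extract_beats <- function(sim) {
  ts <- sim$timeseries
  if (sim$config$variable_hr) {
    s <- ts$s
    ks <- seq(ceiling(min(s)), floor(max(s)))
    if (length(ks) < 2) {
      warning("fewer than 2 complete beats in the simulation")
      return(.empty_beats())
    }
    bounds <- stats::approx(s, ts$t, xout = ks, ties = "ordered")$y
    beat_of <- findInterval(ts$s, ks)
    keep <- beat_of >= 1 & beat_of < length(ks)
    ids <- beat_of[keep]
  } else {
    period <- 60 / sim$bundle$driver$hr
    n_beats <- floor(max(ts$t) / period + 1e-9)
    if (n_beats < 2) {
      warning("fewer than 2 complete beats in the simulation")
      return(.empty_beats())
    }
    bounds <- (0:n_beats) * period
    beat_of <- pmin(floor(ts$t / period + 1e-9) + 1, n_beats + 1)
    keep <- beat_of <= n_beats
    ids <- beat_of[keep]
  }
  df <- ts[keep, ]
  df$beat <- ids
  out <- df |>
    dplyr::group_by(.data$beat) |>
    dplyr::summarise(
      SV_lv = max(.data$V_lv) - min(.data$V_lv),
      SV_rv = max(.data$V_rv) - min(.data$V_rv),
      P_ao_sys = max(.data$P_ao),
      P_ao_dia = min(.data$P_ao),
      inspiration = if ("dV_alv_dt" %in% names(df)) {
        dplyr::first(.data$dV_alv_dt) > 0
      } else NA,
      .groups = "drop")
  out$t_start <- bounds[out$beat]
  out$t_end <- bounds[out$beat + 1]
  out$hr_mean <- 60 / (out$t_end - out$t_start)
  dplyr::relocate(out, "beat", "t_start", "t_end")
}

.empty_beats <- function() {
  tibble::tibble(beat = integer(), t_start = double(), t_end = double(),
                 SV_lv = double(), SV_rv = double(), P_ao_sys = double(),
                 P_ao_dia = double(), inspiration = logical(),
                 hr_mean = double())
}

#' Per-breath respiratory metrics
#'
#' Splits a coupled simulation into breaths, delimited by upward zero
#' crossings of the Lienard pattern variable `y`, and summarises each:
#' mean respiratory muscle pressure, tidal volume (max minus min alveolar
#' volume) and duration.
#'
#' @param sim A `cvr_sim` with a respiratory component.
#' @return A tibble with one row per complete breath: `breath`, `t_start`,
#'   `t_end`, `t_mid`, `duration` (s), `P_mus_mean` (mmHg), `V_tidal` (l).
#' @export
extract_breaths <- function(sim) {
  ts <- sim$timeseries
  if (!"y" %in% names(ts)) {
    stop("no respiratory states in this simulation", call. = FALSE)
  }
  yv <- ts$y
  up <- which(yv[-length(yv)] < 0 & yv[-1] >= 0)
  if (length(up) < 2) {
    return(tibble::tibble(breath = integer(), t_start = double(),
                          t_end = double(), t_mid = double(),
                          duration = double(), P_mus_mean = double(),
                          V_tidal = double()))
  }
  # linear interpolation of each crossing time
  tc <- ts$t[up] + (0 - yv[up]) / (yv[up + 1] - yv[up]) *
    (ts$t[up + 1] - ts$t[up])
  breath_of <- findInterval(ts$t, tc)
  keep <- breath_of >= 1 & breath_of < length(tc)
  df <- ts[keep, ]
  df$breath <- breath_of[keep]
  out <- df |>
    dplyr::group_by(.data$breath) |>
    dplyr::summarise(P_mus_mean = mean(.data$P_mus),
                     V_tidal = max(.data$V_alv) - min(.data$V_alv),
                     .groups = "drop")
  out$t_start <- tc[out$breath]
  out$t_end <- tc[out$breath + 1]
  out$t_mid <- (out$t_start + out$t_end) / 2
  out$duration <- out$t_end - out$t_start
  dplyr::relocate(out, "breath", "t_start", "t_end", "t_mid", "duration")
}

#' Respiratory muscle pressure drift statistic
#'
#' Ordinary least-squares slope of the per-breath mean respiratory muscle
#' pressure against breath mid-time. A stationary (stabilized) respiratory
#' model gives a slope near zero; the original formulation drifts upward.
#'
#' @param sim A `cvr_sim` with a respiratory component.
#' @param t_min,t_max Optional window (s) on the breath mid-times, used to
#'   exclude the initial transient.
#' @return Slope, mmHg s^-1.
#' @export
drift_statistic <- function(sim, t_min = NULL, t_max = NULL) {
  br <- extract_breaths(sim)
  if (!is.null(t_min)) br <- br[br$t_mid >= t_min, ]
  if (!is.null(t_max)) br <- br[br$t_mid <= t_max, ]
  if (nrow(br) < 5) {
    stop("drift statistic needs at least 5 complete breaths (got ",
         nrow(br), ")", call. = FALSE)
  }
  unname(stats::coef(stats::lm(P_mus_mean ~ t_mid, data = br))[2])
}
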