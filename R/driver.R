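#' Cardiac driver function, constant heart rate
#'
#' Gaussian-sum time-varying elastance activation
#' `e(t) = sum_i A_i exp(-B_i ((t mod 60/hr) - C_i)^2)`, periodic with the
#' cardiac period 60/hr seconds. With a single term and `A = 1` the driver
#' stays in `[0, 1]`, peaking at the offset `C` (half a period for
#' continuity across the cycle boundary).
#'
#' @param t Time, s (vectorised).
#' @param cfg A [driver_config()].
#' @param hr Heart rate, min^-1; defaults to the configuration's rate.
#' @return Activation in `[0, 1]` for `N = 1`, `A = 1`.
#' @export
#' @examples
#' cfg <- driver_config(hr = 80)
#' cardiac_driver(0.375, cfg)  # 1 at the pulse peak
cardiac_driver <- function(t, cfg, hr = cfg$hr) {
  if (hr <= 0) stop("heart rate must be positive", call. = FALSE)
  period <- 60 / hr
  tau <- t %% period
  e <- 0
  for (i in seq_len(cfg$N)) {
    e <- e + cfg$A[i] * exp(-cfg$B[i] * (tau - cfg$C[i])^2)
  }
  e
}

#' Wrap a cardiac phase count onto the unit cycle
#'
#' @param s Cardiac phase (count of elapsed cycles), beats, `>= 0`.
#' @return `s mod 1`, in `[0, 1)`.
#' @export
wrap_phase <- function(s) s %% 1

#' Cardiac driver function, variable heart rate (unit-period form)
#'
#' Evaluates the Gaussian-sum driver on the wrapped cardiac phase
#' `s_w in [0, 1)`: `e = sum_i A_hat_i exp(-B_hat_i (s_w - C_hat_i)^2)`.
#' The coefficients are tuned for a cardiac period of 1 s; time warping
#' through the phase state makes this a strict generalisation of the
#' constant-rate driver (`B = B_hat (hr/60)^2` recovers it exactly).
#'
#' @param s_w Wrapped phase in `[0, 1)` (vectorised).
#' @param cfg A [driver_config()].
#' @return Activation value(s).
#' @export
cardiac_driver_phase <- function(s_w, cfg) {
  e <- 0
  for (i in seq_len(cfg$N)) {
    e <- e + cfg$A_hat[i] * exp(-cfg$B_hat[i] * (s_w - cfg$C_hat[i])^2)
  }
  e
}

#' Heart-rate profiles
#'
#' Constructors for the heart-rate source HR(t) driving the cardiac phase
#' state. `hr_constant` is a fixed rate; `hr_tanh_ramp` is the smooth
#' sigmoid ramp `base + amplitude * tanh(rate * (t - center))` used for the
#' variable-rate demonstration (defaults ramp from 60 to 100 min^-1 around
#' t = 20 s); `hr_sampled` linearly interpolates a measured trace with
#' constant extrapolation outside the sampled range.
#'
#' @param value Constant heart rate, min^-1.
#' @param base,amplitude,rate,center Ramp parameters (min^-1, min^-1, s^-1, s).
#' @param samples A data frame with columns `t_s` (s, strictly increasing)
#'   and `hr_min` (min^-1, all positive), at least two rows.
#' @return A list of class `cvr_hr_profile`; evaluate with
#'   [hr_at()] or [phase_derivative()].
#' @name hr-profiles
NULL

#' @rdname hr-profiles
#' @export
hr_constant <- function(value) {
  stopifnot(value > 0)
  structure(list(kind = "constant", value = value), class = "cvr_hr_profile")
}

#' @rdname hr-profiles
#' @export
hr_tanh_ramp <- function(base = 80, amplitude = 20, rate = 0.3, center = 20) {
  stopifnot(base - abs(amplitude) > 0)
  structure(list(kind = "tanh_ramp", base = base, amplitude = amplitude,
                 rate = rate, center = center),
            class = "cvr_hr_profile")
}

#' @rdname hr-profiles
#' @export
hr_sampled <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("t_s", "hr_min") %in% names(samples)))
  if (nrow(samples) < 2) {
    stop("a sampled HR profile needs at least two points", call. = FALSE)
  }
  if (any(diff(samples$t_s) <= 0)) {
    stop("sample times must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  if (any(samples$hr_min <= 0)) {
    stop("heart rate samples must be positive", call. = FALSE)
  }
  structure(list(kind = "sampled", samples = tibble::as_tibble(samples)),
            class = "cvr_hr_profile")
}

#' Evaluate a heart-rate profile
#'
#' @param profile A `cvr_hr_profile`.
#' @param t Time, s (vectorised).
#' @return Heart rate, min^-1.
#' @export
hr_at <- function(profile, t) {
  switch(profile$kind,
    constant = rep_len(profile$value, length(t)),
    tanh_ramp = profile$base +
      profile$amplitude * tanh(profile$rate * (t - profile$center)),
    sampled = stats::approx(profile$samples$t_s, profile$samples$hr_min,
                            xout = t, method = "linear", rule = 2)$y,
    stop("unknown HR profile kind: ", profile$kind, call. = FALSE)
  )
}

#' Cardiac phase derivative
#'
#' The phase state s counts elapsed cardiac cycles, so its derivative is
#' the instantaneous rate in cycles per second, `HR(t)/60`.
#'
#' @inheritParams hr_at
#' @return ds/dt, beats s^-1.
#' @export
phase_derivative <- function(t, profile) hr_at(profile, t) / 60

#' Read and write heart-rate trace files
#'
#' Two-column delimited text with header `t_s,hr_min` (time in seconds,
#' heart rate in min^-1). Values round-trip bit-exactly.
#'
#' @param trace A data frame with columns `t_s`, `hr_min`.
#' @param path File path.
#' @return `write_hr_trace` returns `path` invisibly; `read_hr_trace`
#'   returns a tibble.
#' @name hr-trace-io
NULL

#' @rdname hr-trace-io
#' @export
write_hr_trace <- function(trace, path) {
  stopifnot(all(c("t_s", "hr_min") %in% names(trace)))
  readr::write_csv(trace[c("t_s", "hr_min")], path)
  invisible(path)
}

#' @rdname hr-trace-io
#' @export
read_hr_trace <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  stopifnot(all(c("t_s", "hr_min") %in% names(df)))
  tibble::as_tibble(df)
}

#' Synthetic heart-rate trace fixtures
#'
#' Deterministic generator of heart-rate traces for testing and
#' demonstration: a constant rate, a linear ramp, the tanh ramp of the
#' variable-rate demonstration sampled at 1 Hz, and an ICU-like bounded
#' AR(1) random walk around 80 min^-1 (clamped to `[40, 180]`).
#'
#' @param kind One of `"constant"`, `"linear_ramp"`, `"tanh_ramp"`,
#'   `"random_walk"`.
#' @param seed Integer seed fixing the random walk.
#' @param t_end Trace duration, s.
#' @param dt Sampling interval, s.
#' @return A tibble with columns `t_s`, `hr_min`.
#' @export
hr_trace_fixture <- function(kind = c("constant", "linear_ramp", "tanh_ramp",
                                      "random_walk"),
                             seed = 1, t_end = 60, dt = 1) {
  kind <- match.arg(kind)
  t <- seq(0, t_end, by = dt)
  hr <- switch(kind,
    constant = rep_len(80, length(t)),
    linear_ramp = 60 + (100 - 60) * t / max(t),
    tanh_ramp = hr_at(hr_tanh_ramp(), t),
    random_walk = {
      old <- .Random.seed_safe_get()
      on.exit(.Random.seed_safe_restore(old), add = TRUE)
      set.seed(seed)
      n <- length(t)
      hr <- numeric(n)
      hr[1] <- 80
      for (i in seq_len(n - 1)) {
        # mean-reverting walk: phi pulls back to 80, sd 1.5 per second
        hr[i + 1] <- 80 + 0.98 * (hr[i] - 80) + stats::rnorm(1, 0, 1.5)
      }
      pmin(pmax(hr, 40), 180)
    })
  tibble::tibble(t_s = t, hr_min = hr)
}

.Random.seed_safe_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_safe_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
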