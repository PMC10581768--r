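#' Simulate the coupled cardiovascular-respiratory model
#'
#' Assembles the model right-hand side selected by the bundle and mode
#' flags and integrates it with an embedded adaptive explicit Runge-Kutta
#' 4(5) pair (Dormand-Prince with proportional step control and the
#' standard continuous extension), then samples the dense solution onto a
#' regular grid. All derived signals (pressures, flows, activation, septum
#' volume, pleural pressure) are recomputed from the gridded states by the
#' same right-hand-side code, so the reported waveforms and the integrated
#' dynamics share a single source of truth.
#'
#' Model variants:
#' * valve law: non-inertial check valves, or inertial 'open on pressure,
#'   close on flow' (chosen by the presence of inductances in the bundle);
#' * septum solve: full nonlinear Newton (`"nonlinear"`) or closed-form
#'   linearised (`"linearized"`);
#' * respiration: `"none"` (constant pleural pressure), `"original"`
#'   (Hering-Breuer feedback, no muscle-pressure leak) or `"stabilized"`
#'   (integral feedback on the muscle pressure);
#' * heart rate: constant (driver evaluated on wall-clock time) or
#'   variable (a cardiac phase state integrates HR(t)/60 and the
#'   unit-period driver is evaluated on the wrapped phase).
#'
#' @param bundle A `cvr_bundle`, e.g. from [cvr_preset()].
#' @param t_end Duration, s.
#' @param grid_dt Output sampling interval, s.
#' @param atol,rtol Absolute/relative solver tolerances.
#' @param max_steps Cap on total solver steps (accepted plus rejected).
#' @param septum `"nonlinear"` or `"linearized"`; default nonlinear for the
#'   Smith presets and linearised for the Jallon presets (matching the
#'   original implementations).
#' @param respiration `"none"`, `"original"` or `"stabilized"`; default
#'   stabilized when the bundle has a respiratory component, none
#'   otherwise.
#' @param hr_profile `NULL` for constant-HR mode (rate taken from the
#'   bundle's driver), or a [hr_constant()]/[hr_tanh_ramp()]/[hr_sampled()]
#'   profile, which switches on the variable-HR phase state.
#' @return A `cvr_sim` object: list with `timeseries` (tibble, one row per
#'   grid sample: states then derived signals), `bundle`, `config`, and
#'   `meta` (solver diagnostics, septum-solver iteration statistics,
#'   conservation error, minimum valve flow).
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cvs(cvr_preset("smith_noninertial"), t_end = 5)
#' dplyr::glimpse(sim$timeseries)
#' }
simulate_cvs <- function(bundle, t_end = 60, grid_dt = 0.01,
                         atol = 1e-7, rtol = 1e-4, max_steps = 65536,
                         septum = NULL, respiration = NULL,
                         hr_profile = NULL) {
  viol <- cvr_validate(bundle)
  if (nrow(viol) > 0) {
    stop("invalid parameter bundle: ",
         paste(viol$field, viol$rule, sep = " ", collapse = "; "),
         call. = FALSE)
  }
  stopifnot(t_end > 0, grid_dt > 0, atol > 0, rtol > 0)
  has_resp <- !is.null(bundle$respiratory)
  septum <- if (is.null(septum)) {
    if (has_resp) "linearized" else "nonlinear"
  } else match.arg(septum, c("nonlinear", "linearized"))
  respiration <- if (is.null(respiration)) {
    if (has_resp) "stabilized" else "none"
  } else match.arg(respiration, c("none", "original", "stabilized"))
  if (respiration != "none" && !has_resp) {
    stop("bundle has no respiratory parameters; use respiration = 'none'",
         call. = FALSE)
  }
  inertial <- !is.null(bundle$circulation$valves$mt$L)
  variable_hr <- !is.null(hr_profile)
  if (variable_hr) stopifnot(inherits(hr_profile, "cvr_hr_profile"))

  ctx <- .build_context(bundle, septum, respiration, inertial,
                        variable_hr, hr_profile)
  y0 <- .initial_state(bundle, ctx)

  times <- seq(0, t_end, by = grid_dt)
  rhs <- ctx$eval_rhs
  sol <- .integrate_dp45(function(t, y) rhs(t, y, FALSE), unname(y0), times,
                         atol = atol, rtol = rtol, max_steps = max_steps)

  ts <- .assemble_timeseries(times, sol$y, ctx)
  vol_sum <- ts$V_pa + ts$V_pu + ts$V_lv + ts$V_ao + ts$V_vc + ts$V_rv
  qcols <- c("Q_mt", "Q_av", "Q_tc", "Q_pv")
  meta <- list(
    solver = "dopri5(4)",
    steps_accepted = sol$steps_accepted,
    steps_rejected = sol$steps_rejected,
    fevals = sol$fevals,
    newton = list(evals = ctx$n_solves, total_iterations = ctx$iter_sum,
                  max_iterations = ctx$iter_max,
                  bisection_fallbacks = ctx$fallbacks),
    conservation_error = max(abs(vol_sum - bundle$circulation$V_tot)),
    min_valve_flow = min(as.matrix(ts[qcols]))
  )
  structure(list(
    timeseries = ts,
    bundle = bundle,
    config = list(preset = bundle$name, t_end = t_end, grid_dt = grid_dt,
                  atol = atol, rtol = rtol, max_steps = max_steps,
                  septum = septum, respiration = respiration,
                  inertial = inertial, variable_hr = variable_hr,
                  hr_profile = hr_profile),
    meta = meta
  ), class = "cvr_sim")
}

# Context: state layout, solver bookkeeping and the fused right-hand side.
.build_context <- function(bundle, septum, respiration, inertial,
                           variable_hr, hr_profile) {
  ctx <- new.env(parent = emptyenv())
  ctx$bundle <- bundle
  ctx$septum <- septum
  ctx$respiration <- respiration
  ctx$inertial <- inertial
  ctx$variable_hr <- variable_hr
  ctx$hr_profile <- hr_profile
  nm <- c("V_pa", "V_pu", "V_lv", "V_ao", "V_vc", "V_rv")
  if (inertial) nm <- c(nm, "Q_mt", "Q_av", "Q_tc", "Q_pv")
  if (respiration != "none") nm <- c(nm, "x", "y", "P_mus", "V_alv")
  if (variable_hr) nm <- c(nm, "s")
  ctx$state_names <- nm
  ctx$i_resp <- if (respiration != "none") (6 + 4 * inertial) + 1:4
  ctx$i_s <- if (variable_hr) length(nm)
  ctx$guess <- 0
  ctx$n_solves <- 0L
  ctx$iter_sum <- 0L
  ctx$iter_max <- 0L
  ctx$fallbacks <- 0L
  ctx$eval_rhs <- .make_rhs(bundle, ctx)
  ctx
}

# Fused model evaluation: derivatives of the full coupled state and,
# on request, every derived signal. All parameters are captured as scalar
# locals; the per-operation exported functions implement the identical
# laws and are held equal to this path by the test suite.
.make_rhs <- function(bundle, ctx) {
  w <- bundle$walls
  ees_l <- w$lvf$E_es; vd_l <- w$lvf$V_d; v0_l <- w$lvf$V_0
  lam_l <- w$lvf$lam; p0_l <- w$lvf$P_0
  ees_r <- w$rvf$E_es; vd_r <- w$rvf$V_d; v0_r <- w$rvf$V_0
  lam_r <- w$rvf$lam; p0_r <- w$rvf$P_0
  ees_s <- w$spt$E_es; vd_s <- w$spt$V_d; v0_s <- w$spt$V_0
  lam_s <- w$spt$lam; p0_s <- w$spt$P_0
  v0_p <- w$pcd$V_0; lam_p <- w$pcd$lam; p0_p <- w$pcd$P_0
  kap_l <- lam_l * p0_l; kap_r <- lam_r * p0_r; kap_s <- lam_s * p0_s
  ves <- bundle$vessels
  E_pa <- ves$pa$E; Vd_pa <- ves$pa$V_d
  E_pu <- ves$pu$E; Vd_pu <- ves$pu$V_d
  E_ao <- ves$ao$E; Vd_ao <- ves$ao$V_d
  E_vc <- ves$vc$E; Vd_vc <- ves$vc$V_d
  va <- bundle$circulation$valves
  R_mt <- va$mt$R; R_av <- va$av$R; R_tc <- va$tc$R; R_pv <- va$pv$R
  L_mt <- va$mt$L; L_av <- va$av$L; L_tc <- va$tc$L; L_pv <- va$pv$L
  R_pul <- bundle$circulation$R_pul; R_sys <- bundle$circulation$R_sys
  P_pl_const <- bundle$circulation$P_pl_const
  drv <- bundle$driver
  dN <- drv$N; dA <- drv$A; dB <- drv$B; dC <- drv$C
  dAh <- drv$A_hat; dBh <- drv$B_hat; dCh <- drv$C_hat
  period <- 60 / drv$hr
  rp <- bundle$respiratory
  if (!is.null(rp)) {
    E_alv <- rp$E_alv; E_cw <- rp$E_cw; R_aw <- rp$R_ca + rp$R_ua
    V_th0 <- rp$V_th0; HB <- rp$HB; lmus <- rp$lam_mus; mu <- rp$mu
    beta <- rp$beta; a_li <- rp$a; b_li <- rp$b; alpha <- rp$alpha
  }
  inertial <- ctx$inertial
  resp_mode <- ctx$respiration
  variable_hr <- ctx$variable_hr
  septum_nl <- ctx$septum == "nonlinear"
  hr_profile <- ctx$hr_profile
  i_resp <- ctx$i_resp
  i_s <- ctx$i_s
  nstate <- length(ctx$state_names)
  walls <- bundle$walls

  function(t, y, derived = FALSE) {
    V_pa <- y[1]; V_pu <- y[2]; V_lv <- y[3]
    V_ao <- y[4]; V_vc <- y[5]; V_rv <- y[6]

    # cardiac activation
    if (variable_hr) {
      sw <- y[i_s] %% 1
      e <- sum(dAh * exp(-dBh * (sw - dCh)^2))
    } else {
      tau <- t %% period
      e <- sum(dA * exp(-dB * (tau - dC)^2))
    }

    # respiratory mechanics and pattern generator
    if (resp_mode != "none") {
      x_li <- y[i_resp[1]]; y_li <- y[i_resp[2]]
      P_mus <- y[i_resp[3]]; V_alv <- y[i_resp[4]]
      V_bth <- V_lv + V_rv + V_pu + V_pa
      V_th <- V_bth + V_alv
      P_pl <- P_mus + E_cw * (V_th - V_th0)
      dV_alv <- -(P_pl + E_alv * V_alv) / R_aw
      f_li <- (a_li * y_li^2 + b_li * y_li) * (x_li + y_li)
      if (resp_mode == "original") {
        dresp <- c(alpha * (f_li - HB * dV_alv), alpha * x_li,
                   lmus * y_li + mu, dV_alv)
      } else {
        dresp <- c(alpha * f_li, alpha * x_li,
                   lmus * y_li + mu - beta * P_mus, dV_alv)
      }
    } else {
      P_pl <- P_pl_const
      dresp <- NULL
    }

    # septum volume: closed-form linearised, or warm-started Newton
    one_e <- 1 - e
    if (!septum_nl) {
      num <- e * (ees_l * (V_lv - vd_l) - ees_r * (V_rv - vd_r) +
                    ees_s * vd_s) +
        one_e * (kap_l * (V_lv - v0_l) - kap_r * (V_rv - v0_r) +
                   kap_s * v0_s)
      den <- e * (ees_l + ees_r + ees_s) + one_e * (kap_l + kap_r + kap_s)
      v <- num / den
      it <- 0L
    } else {
      v <- ctx$guess
      it <- -1L
      for (k in 1:20) {
        el <- exp(lam_l * (V_lv - v - v0_l))
        er <- exp(lam_r * (V_rv + v - v0_r))
        es <- exp(lam_s * (v - v0_s))
        fv <- e * (ees_l * (V_lv - v - vd_l) - ees_r * (V_rv + v - vd_r) -
                     ees_s * (v - vd_s)) +
          one_e * (p0_l * (el - 1) - p0_r * (er - 1) - p0_s * (es - 1))
        if (is.na(fv)) break
        if (abs(fv) <= 1e-9) { it <- k - 1L; break }
        fp <- -(e * (ees_l + ees_r + ees_s) +
                  one_e * (kap_l * el + kap_r * er + kap_s * es))
        v <- v - fv / fp
      }
      if (it < 0L) {
        # rare: stale warm start or wild trial state; robust fallback
        v <- tryCatch(as.numeric(solve_septum(V_lv, V_rv, e, walls,
                                              guess = 0)),
                      error = function(err) NaN)
        it <- 21L
        if (is.nan(v)) {
          if (derived) {
            stop("septum solve failed on a gridded state", call. = FALSE)
          }
          return(rep(NaN, nstate))
        }
      }
      ctx$guess <- v
    }
    ctx$n_solves <- ctx$n_solves + 1L
    ctx$iter_sum <- ctx$iter_sum + it
    if (it > ctx$iter_max) ctx$iter_max <- it
    if (it > 20L) ctx$fallbacks <- ctx$fallbacks + 1L

    # chamber and vessel pressures (full nonlinear laws)
    V_lvf <- V_lv - v
    V_rvf <- V_rv + v
    P_lvf <- e * ees_l * (V_lvf - vd_l) + one_e * p0_l * expm1(lam_l * (V_lvf - v0_l))
    P_rvf <- e * ees_r * (V_rvf - vd_r) + one_e * p0_r * expm1(lam_r * (V_rvf - v0_r))
    P_peri <- p0_p * expm1(lam_p * (V_lv + V_rv - v0_p)) + P_pl
    P_lv <- P_lvf + P_peri
    P_rv <- P_rvf + P_peri
    P_pa <- E_pa * (V_pa - Vd_pa) + P_pl
    P_pu <- E_pu * (V_pu - Vd_pu) + P_pl
    P_ao <- E_ao * (V_ao - Vd_ao)
    P_vc <- E_vc * (V_vc - Vd_vc)

    # valve and circulation flows
    if (inertial) {
      Q_mt <- y[7]; Q_av <- y[8]; Q_tc <- y[9]; Q_pv <- y[10]
      dQ <- c(
        if (Q_mt > 0 || P_pu > P_lv) (P_pu - P_lv - Q_mt * R_mt) / L_mt else 0,
        if (Q_av > 0 || P_lv > P_ao) (P_lv - P_ao - Q_av * R_av) / L_av else 0,
        if (Q_tc > 0 || P_vc > P_rv) (P_vc - P_rv - Q_tc * R_tc) / L_tc else 0,
        if (Q_pv > 0 || P_rv > P_pa) (P_rv - P_pa - Q_pv * R_pv) / L_pv else 0)
      rQ_mt <- max(Q_mt, 0); rQ_av <- max(Q_av, 0)
      rQ_tc <- max(Q_tc, 0); rQ_pv <- max(Q_pv, 0)
    } else {
      rQ_mt <- Q_mt <- max((P_pu - P_lv) / R_mt, 0)
      rQ_av <- Q_av <- max((P_lv - P_ao) / R_av, 0)
      rQ_tc <- Q_tc <- max((P_vc - P_rv) / R_tc, 0)
      rQ_pv <- Q_pv <- max((P_rv - P_pa) / R_pv, 0)
      dQ <- NULL
    }
    Q_pul <- (P_pa - P_pu) / R_pul
    Q_sys <- (P_ao - P_vc) / R_sys

    dstate <- c(rQ_pv - Q_pul,   # pa
                Q_pul - rQ_mt,   # pu
                rQ_mt - rQ_av,   # lv
                rQ_av - Q_sys,   # ao
                Q_sys - rQ_tc,   # vc
                rQ_tc - rQ_pv,   # rv
                dQ, dresp,
                if (variable_hr) hr_at(hr_profile, t) / 60)
    if (!derived) return(dstate)
    der <- list(e = e, V_spt = v, P_pl = P_pl,
                P_lv = P_lv, P_rv = P_rv, P_peri = P_peri,
                P_pa = P_pa, P_pu = P_pu, P_ao = P_ao, P_vc = P_vc,
                Q_mt = Q_mt, Q_av = Q_av, Q_tc = Q_tc, Q_pv = Q_pv,
                Q_pul = Q_pul, Q_sys = Q_sys)
    if (resp_mode != "none") {
      der$V_bth <- V_bth
      der$V_th <- V_th
      der$dV_alv_dt <- dV_alv
    }
    list(dstate = dstate, derived = der)
  }
}

.initial_state <- function(bundle, ctx) {
  ini <- bundle$initial
  y0 <- unname(ini$volumes[c("pa", "pu", "lv", "rv", "ao", "vc")])
  y0 <- y0[c(1, 2, 3, 5, 6, 4)]  # reorder to pa, pu, lv, ao, vc, rv
  V_alv0 <- NULL
  if (ctx$respiration != "none") {
    V_alv0 <- if (!is.null(ini$V_alv)) ini$V_alv else default_v_alv(bundle)
  }
  e0 <- if (ctx$variable_hr) {
    cardiac_driver_phase(ini$s %% 1, bundle$driver)
  } else {
    cardiac_driver(0, bundle$driver)
  }
  if (ctx$inertial) {
    if (!is.null(ini$flows)) {
      q0 <- unname(ini$flows[c("mt", "av", "tc", "pv")])
    } else {
      # zero-inertia initial flows, clipped to the open direction
      P_pl0 <- if (ctx$respiration != "none") {
        V_bth <- sum(y0[c(1, 2, 3, 6)])
        pleural_pressure(ini$P_mus, V_bth + V_alv0, bundle$respiratory)
      } else {
        bundle$circulation$P_pl_const
      }
      guess0 <- solve_septum_linearized(y0[3], y0[6], e0, bundle$walls)
      hp <- heart_pressures(y0[3], y0[6], e0, P_pl0, bundle$walls,
                            mode = ctx$septum, guess = guess0)
      ves <- bundle$vessels
      P_pa <- ves$pa$E * (y0[1] - ves$pa$V_d) + P_pl0
      P_pu <- ves$pu$E * (y0[2] - ves$pu$V_d) + P_pl0
      P_ao <- ves$ao$E * (y0[4] - ves$ao$V_d)
      P_vc <- ves$vc$E * (y0[5] - ves$vc$V_d)
      va <- bundle$circulation$valves
      q0 <- pmax(c((P_pu - hp$P_lv) / va$mt$R,
                   (hp$P_lv - P_ao) / va$av$R,
                   (P_vc - hp$P_rv) / va$tc$R,
                   (hp$P_rv - P_pa) / va$pv$R), 0)
    }
    y0 <- c(y0, q0)
  }
  if (ctx$respiration != "none") {
    y0 <- c(y0, ini$x, ini$y, ini$P_mus, V_alv0)
  }
  if (ctx$variable_hr) y0 <- c(y0, ini$s)
  # initialise the septum warm start from the closed-form solution
  ctx$guess <- solve_septum_linearized(y0[3], y0[6], e0, bundle$walls)
  stats::setNames(y0, ctx$state_names)
}

.assemble_timeseries <- function(t, states, ctx) {
  colnames(states) <- ctx$state_names
  n <- length(t)
  rhs <- ctx$eval_rhs
  first <- rhs(t[1], states[1, ], derived = TRUE)$derived
  dn <- names(first)
  der <- matrix(NA_real_, nrow = n, ncol = length(dn),
                dimnames = list(NULL, dn))
  der[1, ] <- unlist(first)
  for (i in 2:n) {
    der[i, ] <- unlist(rhs(t[i], states[i, ], derived = TRUE)$derived)
  }
  # in inertial mode the valve flows are states; drop the duplicate columns
  dup <- intersect(colnames(der), colnames(states))
  if (length(dup)) der <- der[, setdiff(colnames(der), dup), drop = FALSE]
  tibble::as_tibble(cbind(data.frame(t = t), states, der))
}

#' @export
print.cvr_sim <- function(x, ...) {
  cat("<cvr_sim>", x$config$preset, "\n")
  cat(sprintf("  %.4g s at dt = %g s (%d samples); valves %s; septum %s; respiration %s; HR %s\n",
              x$config$t_end, x$config$grid_dt, nrow(x$timeseries),
              if (x$config$inertial) "inertial" else "non-inertial",
              x$config$septum, x$config$respiration,
              if (x$config$variable_hr) "variable" else "constant"))
  cat(sprintf("  conservation error %.3g l; min valve flow %.3g l/s\n",
              x$meta$conservation_error, x$meta$min_valve_flow))
  invisible(x)
}
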