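#' Ventricular pressure-volume laws
#'
#' The end-systolic pressure-volume relationship (ESPVR) is linear,
#' `P = E_es (V - V_d)`; the end-diastolic relationship (EDPVR) is
#' exponential, `P = P_0 (exp(lam (V - V_0)) - 1)`; and the instantaneous
#' wall pressure blends the two through the cardiac driver activation,
#' `P = e ESPVR + (1 - e) EDPVR` (time-varying elastance). A passive
#' chamber (no `E_es`) returns the EDPVR regardless of activation.
#' `edpvr_linear` is the first-order EDPVR linearisation
#' `P = P_0 lam (V - V_0)` used in the closed-form septum solution.
#'
#' @param V Volume, l (vectorised).
#' @param p A [chamber_params()].
#' @param e Activation in `[0, 1]`.
#' @return Pressure, mmHg.
#' @name pv-laws
NULL

#' @rdname pv-laws
#' @export
espvr_pressure <- function(V, p) {
  stopifnot(!is.null(p$E_es))
  p$E_es * (V - p$V_d)
}

#' @rdname pv-laws
#' @export
edpvr_pressure <- function(V, p) {
  p$P_0 * (exp(p$lam * (V - p$V_0)) - 1)
}

#' @rdname pv-laws
#' @export
edpvr_linear <- function(V, p) {
  p$P_0 * p$lam * (V - p$V_0)
}

#' @rdname pv-laws
#' @export
wall_pressure <- function(V, e, p) {
  ed <- edpvr_pressure(V, p)
  if (is.null(p$E_es)) return(ed)
  e * espvr_pressure(V, p) + (1 - e) * ed
}

# scalar fast paths used inside the ODE right-hand side ----------------------

.wall_p <- function(V, e, E_es, V_d, V_0, lam, P_0) {
  e * E_es * (V - V_d) + (1 - e) * P_0 * (expm1(lam * (V - V_0)))
}

.wall_dp <- function(V, e, E_es, V_0, lam, P_0) {
  e * E_es + (1 - e) * P_0 * lam * exp(lam * (V - V_0))
}

#' Septum volume residual
#'
#' The ventricular-interaction coupling requires the septal free-wall
#' volume `V_spt` to satisfy a pressure balance between the two ventricle
#' free walls and the septum: the residual
#' `f(V_spt) = P_lvf(V_lv - V_spt) - P_rvf(V_rv + V_spt) - P_spt(V_spt)`
#' is zero at the physical septum deflection. All three wall pressures use
#' the full nonlinear laws. `f` is strictly decreasing in `V_spt` for
#' positive parameters, so the root is unique.
#'
#' @param V_spt Trial septum volume, l.
#' @param V_lv,V_rv Left/right ventricle volumes, l.
#' @param e Activation in `[0, 1]`.
#' @param walls Named list of [chamber_params()] with elements `lvf`,
#'   `rvf`, `spt` (and `pcd`, unused here).
#' @return Residual pressure, mmHg.
#' @export
septum_residual <- function(V_spt, V_lv, V_rv, e, walls) {
  wall_pressure(V_lv - V_spt, e, walls$lvf) -
    wall_pressure(V_rv + V_spt, e, walls$rvf) -
    wall_pressure(V_spt, e, walls$spt)
}

#' Solve the septum volume (nonlinear)
#'
#' Newton-Raphson on [septum_residual()] with the analytic derivative,
#' warm-started from `guess` (in a simulation, the solution accepted at the
#' previous step, from which convergence typically takes one or two
#' iterations). If Newton fails to converge within `max_iter` iterations, a
#' bracket is grown geometrically around the guess and the root is
#' recovered by bisection.
#'
#' @inheritParams septum_residual
#' @param guess Starting value, l.
#' @param tol Convergence tolerance on `|f|`, mmHg.
#' @param max_iter Newton iteration cap.
#' @return The septum volume root, l, with attribute `iterations`.
#' @export
solve_septum <- function(V_lv, V_rv, e, walls, guess = 0,
                         tol = 1e-9, max_iter = 20) {
  l <- walls$lvf; r <- walls$rvf; s <- walls$spt
  f <- function(v) {
    .wall_p(V_lv - v, e, l$E_es, l$V_d, l$V_0, l$lam, l$P_0) -
      .wall_p(V_rv + v, e, r$E_es, r$V_d, r$V_0, r$lam, r$P_0) -
      .wall_p(v, e, s$E_es, s$V_d, s$V_0, s$lam, s$P_0)
  }
  fp <- function(v) {
    -.wall_dp(V_lv - v, e, l$E_es, l$V_0, l$lam, l$P_0) -
      .wall_dp(V_rv + v, e, r$E_es, r$V_0, r$lam, r$P_0) -
      .wall_dp(v, e, s$E_es, s$V_0, s$lam, s$P_0)
  }
  v <- guess
  if (!is.finite(f(v))) {
    # stale warm start (e.g. after a rejected wild trial step): re-seed
    # from the closed-form linearised solution
    v <- solve_septum_linearized(V_lv, V_rv, e, walls)
  }
  guess <- v
  for (it in seq_len(max_iter)) {
    fv <- f(v)
    if (is.finite(fv) && abs(fv) <= tol) {
      return(structure(v, iterations = it - 1L))
    }
    step <- fv / fp(v)
    if (!is.finite(step)) break
    v <- v - step
  }
  # bisection fallback on a geometrically grown bracket around the guess
  w <- 1e-3
  lo <- guess - w; hi <- guess + w
  grow <- 0L
  while (is.finite(f(lo)) && is.finite(f(hi)) && f(lo) * f(hi) > 0) {
    w <- w * 2
    lo <- guess - w; hi <- guess + w
    grow <- grow + 1L
    if (grow > 60L) {
      stop(sprintf(paste0("septum solve failed to bracket a root: ",
                          "V_lv=%.6g V_rv=%.6g e=%.6g guess=%.6g"),
                   V_lv, V_rv, e, guess), call. = FALSE)
    }
  }
  for (it in seq_len(200L)) {
    v <- (lo + hi) / 2
    fv <- f(v)
    if (abs(fv) <= tol || (hi - lo) < 1e-15) {
      return(structure(v, iterations = max_iter + it))
    }
    # f is decreasing: positive residual means the root lies to the right
    if (fv > 0) lo <- v else hi <- v
  }
  stop("septum bisection did not converge", call. = FALSE)
}

#' Solve the septum volume (closed-form linearised)
#'
#' Replaces the exponential EDPVR by its first-order linearisation in the
#' septum balance only, which makes the residual affine in `V_spt` and
#' yields the closed-form quotient
#' \deqn{V_{spt} = \frac{e\,(P_{es,lvf}(V_{lv}) - P_{es,rvf}(V_{rv}) +
#'   E_{es,spt} V_{d,spt}) + (1-e)\,(P_{ed,lin,lvf}(V_{lv}) -
#'   P_{ed,lin,rvf}(V_{rv}) + \lambda_{spt} P_{0,spt} V_{0,spt})}
#'   {e\,(E_{es,lvf} + E_{es,rvf} + E_{es,spt}) + (1-e)\,(\lambda_{lvf}
#'   P_{0,lvf} + \lambda_{rvf} P_{0,rvf} + \lambda_{spt} P_{0,spt})}.}
#' The returned value exactly zeroes the residual built with the linear
#' EDPVR substituted for all three walls.
#'
#' @inheritParams septum_residual
#' @return Septum volume, l.
#' @export
solve_septum_linearized <- function(V_lv, V_rv, e, walls) {
  l <- walls$lvf; r <- walls$rvf; s <- walls$spt
  num <- e * (espvr_pressure(V_lv, l) - espvr_pressure(V_rv, r) +
                s$E_es * s$V_d) +
    (1 - e) * (edpvr_linear(V_lv, l) - edpvr_linear(V_rv, r) +
                 s$lam * s$P_0 * s$V_0)
  den <- e * (l$E_es + r$E_es + s$E_es) +
    (1 - e) * (l$lam * l$P_0 + r$lam * r$P_0 + s$lam * s$P_0)
  if (!is.finite(den) || den == 0) {
    stop("linearised septum solve: zero denominator (nonphysical parameters)",
         call. = FALSE)
  }
  num / den
}

#' Ventricular and pericardial pressures
#'
#' Solves the septum volume (nonlinear Newton or closed-form linearised
#' mode), forms the free-wall virtual volumes `V_lvf = V_lv - V_spt`,
#' `V_rvf = V_rv + V_spt`, and assembles the chamber pressures: the passive
#' pericardium sees the total heart volume and the pleural pressure,
#' `P_peri = P_pcd(V_lv + V_rv) + P_pl`, and each ventricle adds the
#' pericardial pressure to its free-wall pressure. Reported wall pressures
#' always use the full nonlinear laws; the linearisation (when selected)
#' enters only the solution for `V_spt`.
#'
#' @inheritParams septum_residual
#' @param P_pl Pleural (thoracic) pressure, mmHg.
#' @param mode `"nonlinear"` or `"linearized"` septum solve.
#' @param guess Warm-start value for the nonlinear solve, l.
#' @return A list with `P_lv`, `P_rv`, `P_peri` (mmHg), `V_spt`, `V_lvf`,
#'   `V_rvf`, `V_pcd` (l), and `iterations` (nonlinear mode).
#' @export
heart_pressures <- function(V_lv, V_rv, e, P_pl, walls,
                            mode = c("nonlinear", "linearized"), guess = 0) {
  mode <- match.arg(mode)
  if (mode == "nonlinear") {
    V_spt <- solve_septum(V_lv, V_rv, e, walls, guess = guess)
    iters <- attr(V_spt, "iterations")
    V_spt <- as.numeric(V_spt)
  } else {
    V_spt <- solve_septum_linearized(V_lv, V_rv, e, walls)
    iters <- 0L
  }
  V_lvf <- V_lv - V_spt
  V_rvf <- V_rv + V_spt
  V_pcd <- V_lv + V_rv
  P_lvf <- wall_pressure(V_lvf, e, walls$lvf)
  P_rvf <- wall_pressure(V_rvf, e, walls$rvf)
  P_peri <- edpvr_pressure(V_pcd, walls$pcd) + P_pl
  list(P_lv = P_lvf + P_peri, P_rv = P_rvf + P_peri, P_peri = P_peri,
       V_spt = V_spt, V_lvf = V_lvf, V_rvf = V_rvf, V_pcd = V_pcd,
       iterations = iters)
}
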