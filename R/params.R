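#' Parameter containers for the cardiovascular-respiratory model
#'
#' Constructors for the typed parameter sets used throughout the package.
#' All quantities use a single global unit convention: time in seconds,
#' volume in litres, pressure in mmHg; heart rate alone is expressed in
#' min^-1 by clinical convention. Conversions, if any, happen at I/O
#' boundaries only.
#'
#' @name cvr-params
NULL

#' Pressure-volume parameters of one cardiac wall or the pericardium
#'
#' A wall is characterised by its end-systolic pressure-volume relationship
#' (ESPVR, linear with contractility `E_es` about the dead-space volume
#' `V_d`) and its end-diastolic relationship (EDPVR, exponential with
#' curvature `lam` and gradient `P_0` about `V_0`). Passive chambers (the
#' pericardium) have no ESPVR: leave `E_es` and `V_d` as `NULL` and the
#' wall pressure is the EDPVR alone, regardless of activation.
#'
#' @param E_es Contractility, mmHg l^-1, or `NULL` for a passive chamber.
#' @param V_d Dead-space volume (zero-ESPVR-pressure volume), l, or `NULL`.
#' @param V_0 Volume at zero EDPVR pressure, l.
#' @param lam EDPVR curvature, l^-1.
#' @param P_0 EDPVR gradient, mmHg.
#' @return A list of class `cvr_chamber`.
#' @export
#' @examples
#' lvf <- chamber_params(E_es = 2879.8, V_d = 0, V_0 = 0, lam = 33, P_0 = 0.1203)
chamber_params <- function(E_es = NULL, V_d = NULL, V_0, lam, P_0) {
  stopifnot(is.null(E_es) == is.null(V_d))
  structure(list(E_es = E_es, V_d = V_d, V_0 = V_0, lam = lam, P_0 = P_0),
            class = "cvr_chamber")
}

#' Linear-elastance vessel compartment parameters
#'
#' @param E Elastance, mmHg l^-1.
#' @param V_d Unstressed (dead-space) volume, l.
#' @param in_thorax Logical; if `TRUE` the pleural pressure is added to this
#'   vessel's pressure (pulmonary artery and vein in the default presets).
#' @return A list of class `cvr_vessel`.
#' @export
vessel_params <- function(E, V_d = 0, in_thorax = FALSE) {
  structure(list(E = E, V_d = V_d, in_thorax = isTRUE(in_thorax)),
            class = "cvr_vessel")
}

#' Valve parameters
#'
#' @param R Resistance, mmHg s l^-1.
#' @param L Inductance, mmHg s^2 l^-1; `NULL` for the non-inertial valve law.
#' @return A list of class `cvr_valve`.
#' @export
valve_params <- function(R, L = NULL) {
  structure(list(R = R, L = L), class = "cvr_valve")
}

#' Circulation-level parameters
#'
#' @param valves Named list of [valve_params()] keyed `mt`, `av`, `tc`, `pv`
#'   (mitral, aortic, tricuspid, pulmonary).
#' @param R_pul,R_sys Pulmonary and systemic circulation resistances,
#'   mmHg s l^-1.
#' @param V_tot Total (or, for the inertial preset, stressed) blood volume, l.
#' @param P_pl_const Constant pleural pressure, mmHg, used when no
#'   respiratory model is attached.
#' @return A list of class `cvr_circulation`.
#' @export
circulation_params <- function(valves, R_pul, R_sys, V_tot, P_pl_const = -4) {
  stopifnot(all(c("mt", "av", "tc", "pv") %in% names(valves)))
  structure(list(valves = valves, R_pul = R_pul, R_sys = R_sys,
                 V_tot = V_tot, P_pl_const = P_pl_const),
            class = "cvr_circulation")
}

#' Cardiac driver configuration
#'
#' The driver is a sum of `N` Gaussian pulses. `A`, `B`, `C` parametrise the
#' constant-heart-rate form (argument in seconds, period 60/HR); `A_hat`,
#' `B_hat`, `C_hat` parametrise the unit-period form evaluated on the
#' wrapped cardiac phase, used with a variable heart rate. With `N = 1`,
#' `A = 1` keeps the activation in `[0, 1]` and `C = 30/HR` (half a period;
#' `C_hat = 0.5`) keeps the pulse continuous across the cycle boundary.
#'
#' @param N Number of Gaussian terms.
#' @param A,B,C Constant-HR coefficients (dimensionless, s^-2, s).
#' @param A_hat,B_hat,C_hat Unit-period coefficients (all dimensionless).
#' @param hr Default constant heart rate, min^-1.
#' @return A list of class `cvr_driver`.
#' @export
driver_config <- function(N = 1, A = 1, B = 80, C = 30 / hr,
                          A_hat = 1, B_hat = 80, C_hat = 0.5, hr = 80) {
  if (N > 1 && (abs(A[1] - 1) > 0 || abs(A_hat[1] - 1) > 0)) {
    # constraints are only stated for N = 1; just flag unusual scalings
    warning("driver with N > 1: no normalisation of A is enforced")
  }
  structure(list(N = N, A = A, B = B, C = C,
                 A_hat = A_hat, B_hat = B_hat, C_hat = C_hat, hr = hr),
            class = "cvr_driver")
}

#' Respiratory model parameters
#'
#' Passive lung/chest-wall mechanics plus the Lienard-oscillator central
#' respiratory pattern generator (CRPG). `HB` weights the Hering-Breuer
#' reflex term of the original CRPG; `beta` is the integral-feedback gain of
#' the stabilized variant. Both are carried so either variant (or an
#' intermediate) can be configured at simulation time.
#'
#' @param E_alv Alveolar elastance, mmHg l^-1.
#' @param E_cw Chest-wall elastance, mmHg l^-1.
#' @param R_ua,R_ca Upper/central airway resistances, mmHg s l^-1.
#' @param V_th0 Intrathoracic volume at zero pressure, l.
#' @param HB Hering-Breuer reflex constant, l^-1.
#' @param lam_mus Gain on the Lienard output in the P_mus derivative,
#'   mmHg s^-1.
#' @param mu Offset in the P_mus derivative, mmHg s^-1.
#' @param beta Integral control gain on P_mus, s^-1.
#' @param a,b Lienard shape parameters, dimensionless.
#' @param alpha Lienard rate constant, s^-1 (sets the oscillator time base).
#' @return A list of class `cvr_respiratory`.
#' @export
respiratory_params <- function(E_alv = 3.678, E_cw = 2.942, R_ua = 3.678,
                               R_ca = 0.7356, V_th0 = 2, HB = 1,
                               lam_mus = 1.5, mu = 1, beta = 0.1,
                               a = -0.8, b = -3, alpha = 1) {
  structure(list(E_alv = E_alv, E_cw = E_cw, R_ua = R_ua, R_ca = R_ca,
                 V_th0 = V_th0, HB = HB, lam_mus = lam_mus, mu = mu,
                 beta = beta, a = a, b = b, alpha = alpha),
            class = "cvr_respiratory")
}

#' Initial conditions
#'
#' @param volumes Named numeric vector of the six compartment volumes (l),
#'   keyed `pa`, `pu`, `lv`, `rv`, `ao`, `vc`. Must sum to the circulation's
#'   total blood volume.
#' @param flows Optional named numeric vector of initial valve flows
#'   (l s^-1) keyed `mt`, `av`, `tc`, `pv`; if `NULL` in inertial mode they
#'   are derived from the initial pressures assuming zero inertia.
#' @param x,y Lienard oscillator states, dimensionless.
#' @param P_mus Respiratory muscle pressure, mmHg.
#' @param V_alv Alveolar volume, l, or `NULL` to use the airflow equilibrium
#'   at the constant pleural pressure, `-P_pl_const / E_alv`.
#' @param s Cardiac phase (count of elapsed cardiac cycles), beats.
#' @return A list of class `cvr_initial`.
#' @export
initial_conditions <- function(volumes, flows = NULL, x = -0.6, y = 0,
                               P_mus = 0, V_alv = NULL, s = 0) {
  stopifnot(all(c("pa", "pu", "lv", "rv", "ao", "vc") %in% names(volumes)))
  structure(list(volumes = volumes[c("pa", "pu", "lv", "rv", "ao", "vc")],
                 flows = flows, x = x, y = y, P_mus = P_mus,
                 V_alv = V_alv, s = s),
            class = "cvr_initial")
}

#' Literature parameter presets
#'
#' Returns a complete, validated parameter bundle (walls, vessels,
#' circulation, cardiac driver, optional respiratory model, initial
#' conditions) transcribed verbatim from the published tables of the Smith
#' ventricular-interaction model and the Jallon heart-lung extension.
#'
#' Available presets:
#' \describe{
#'   \item{`smith_noninertial`}{Six-compartment closed loop with simple
#'     check valves; total blood volume 5.5 l; constant pleural pressure.}
#'   \item{`smith_inertial`}{Same topology with valve inductances
#'     ('open on pressure, close on flow'); stressed blood volume 1.5 l
#'     (unstressed volumes ignored in this parametrisation).}
#'   \item{`jallon`}{Non-inertial loop coupled to the respiratory model
#'     (Lienard CRPG + passive lung/chest wall); HR 80 min^-1.}
#'   \item{`jallon_bracketed`}{As `jallon`, with the alternative
#'     reduced-septal-stiffness values (E_es,spt 3750, lambda_spt 35,
#'     E_vc 2, HR 54) published alongside the main set for reference;
#'     not used for any headline result.}
#' }
#'
#' @param name Preset identifier.
#' @return A list of class `cvr_bundle` with elements `name`, `model`,
#'   `walls`, `vessels`, `circulation`, `driver`, `respiratory` (or `NULL`),
#'   `initial`.
#' @export
#' @examples
#' b <- cvr_preset("smith_noninertial")
#' b$circulation$V_tot
#' sum(b$initial$volumes)
cvr_preset <- function(name = c("smith_noninertial", "smith_inertial",
                                "jallon", "jallon_bracketed")) {
  valid <- c("smith_noninertial", "smith_inertial", "jallon",
             "jallon_bracketed")
  if (length(name) != 1 || !name %in% valid) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(valid, collapse = ", "), call. = FALSE)
  }

  walls_noninertial <- list(
    lvf = chamber_params(E_es = 3405, V_d = 0.005, V_0 = 0.005,
                         lam = 15, P_0 = 1.2751),
    rvf = chamber_params(E_es = 653, V_d = 0.005, V_0 = 0.005,
                         lam = 15, P_0 = 1.2001),
    spt = chamber_params(E_es = 48754, V_d = 0.002, V_0 = 0.002,
                         lam = 435, P_0 = 1.1101),
    pcd = chamber_params(V_0 = 0.2, lam = 30, P_0 = 0.5003)
  )
  vessels_noninertial <- list(
    pa = vessel_params(E = 337.5, V_d = 0.16, in_thorax = TRUE),
    pu = vessel_params(E = 6, V_d = 0.2, in_thorax = TRUE),
    ao = vessel_params(E = 705, V_d = 0.8),
    vc = vessel_params(E = 11.25, V_d = 2.83)
  )
  circ_noninertial <- circulation_params(
    valves = list(mt = valve_params(R = 0.45),
                  av = valve_params(R = 10.5),
                  tc = valve_params(R = 1.35),
                  pv = valve_params(R = 3.6)),
    R_pul = 142.5, R_sys = 1050, V_tot = 5.5, P_pl_const = -4
  )
  vols_noninertial <- c(pa = 0.187, pu = 0.902, lv = 0.1375,
                        rv = 0.132, ao = 0.9515, vc = 3.190)

  bundle <- switch(
    name,
    smith_noninertial = list(
      name = name, model = "smith",
      walls = walls_noninertial, vessels = vessels_noninertial,
      circulation = circ_noninertial,
      driver = driver_config(hr = 80),
      respiratory = NULL,
      initial = initial_conditions(volumes = vols_noninertial)
    ),
    smith_inertial = list(
      name = name, model = "smith",
      walls = list(
        lvf = chamber_params(E_es = 2879.8, V_d = 0, V_0 = 0,
                             lam = 33, P_0 = 0.1203),
        rvf = chamber_params(E_es = 585, V_d = 0, V_0 = 0,
                             lam = 23, P_0 = 0.2157),
        spt = chamber_params(E_es = 48754, V_d = 0.002, V_0 = 0.002,
                             lam = 435, P_0 = 1.1101),
        pcd = chamber_params(V_0 = 0.2, lam = 30, P_0 = 0.5003)
      ),
      vessels = list(
        pa = vessel_params(E = 369, V_d = 0, in_thorax = TRUE),
        pu = vessel_params(E = 7.3, V_d = 0, in_thorax = TRUE),
        ao = vessel_params(E = 691.3, V_d = 0),
        vc = vessel_params(E = 5.9, V_d = 0)
      ),
      circulation = circulation_params(
        valves = list(mt = valve_params(R = 15.8, L = 7.6968e-2),
                      av = valve_params(R = 18, L = 1.2189e-1),
                      tc = valve_params(R = 23.7, L = 8.0093e-2),
                      pv = valve_params(R = 5.5, L = 1.4868e-1)),
        R_pul = 155.2, R_sys = 1088.9, V_tot = 1.5, P_pl_const = -4
      ),
      driver = driver_config(hr = 80),
      respiratory = NULL,
      initial = initial_conditions(
        volumes = c(pa = 0.043, pu = 0.808, lv = 0.095,
                    rv = 0.091, ao = 0.133, vc = 0.330))
    ),
    jallon = list(
      name = name, model = "jallon",
      walls = walls_noninertial, vessels = vessels_noninertial,
      circulation = circ_noninertial,
      driver = driver_config(hr = 80),
      respiratory = respiratory_params(),
      initial = initial_conditions(volumes = vols_noninertial)
    ),
    jallon_bracketed = {
      walls <- walls_noninertial
      walls$spt <- chamber_params(E_es = 3750, V_d = 0.002, V_0 = 0.002,
                                  lam = 35, P_0 = 1.1101)
      vessels <- vessels_noninertial
      vessels$vc <- vessel_params(E = 2, V_d = 2.83)
      list(
        name = name, model = "jallon",
        walls = walls, vessels = vessels,
        circulation = circ_noninertial,
        driver = driver_config(hr = 54),
        respiratory = respiratory_params(),
        initial = initial_conditions(volumes = vols_noninertial)
      )
    }
  )
  structure(bundle, class = "cvr_bundle")
}

#' Default initial alveolar volume for a bundle
#'
#' The airflow equilibrium of the alveolar compartment at the bundle's
#' constant pleural pressure: `V_alv = -P_pl_const / E_alv`.
#'
#' @param bundle A `cvr_bundle` with a respiratory component.
#' @return Alveolar volume, l.
#' @export
default_v_alv <- function(bundle) {
  stopifnot(!is.null(bundle$respiratory))
  -bundle$circulation$P_pl_const / bundle$respiratory$E_alv
}

#' @export
print.cvr_bundle <- function(x, ...) {
  cat("<cvr_bundle>", x$name, "\n")
  cat("  model:", x$model,
      if (is.null(x$circulation$valves$mt$L)) "(non-inertial valves)"
      else "(inertial valves)", "\n")
  cat("  V_tot:", x$circulation$V_tot, "l; HR:", x$driver$hr, "min^-1\n")
  if (!is.null(x$respiratory)) {
    cat("  respiratory: beta =", x$respiratory$beta,
        "s^-1, HB =", x$respiratory$HB, "l^-1\n")
  }
  invisible(x)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the parameter types: sign
#' constraints, presence rules, and consistency of the initial volumes with
#' the total blood volume. Reporting only; never throws.
#'
#' @param bundle A `cvr_bundle`.
#' @return A tibble with columns `field` and `rule`, one row per violation;
#'   zero rows when the bundle is valid.
#' @export
#' @examples
#' nrow(cvr_validate(cvr_preset("jallon")))  # 0
cvr_validate <- function(bundle) {
  field <- character()
  rule <- character()
  bad <- function(f, r) {
    field <<- c(field, f)
    rule <<- c(rule, r)
  }
  num_ok <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)

  for (w in names(bundle$walls)) {
    p <- bundle$walls[[w]]
    if (!is.null(p$E_es) && (!num_ok(p$E_es) || p$E_es < 0)) {
      bad(paste0("walls.", w, ".E_es"), "must be >= 0")
    }
    if (!is.null(p$V_d) && (!num_ok(p$V_d) || p$V_d < 0)) {
      bad(paste0("walls.", w, ".V_d"), "must be >= 0")
    }
    for (f in c("V_0", "lam", "P_0")) {
      if (!num_ok(p[[f]]) || p[[f]] < 0) {
        bad(paste0("walls.", w, ".", f), "must be >= 0")
      }
    }
  }
  for (v in names(bundle$vessels)) {
    p <- bundle$vessels[[v]]
    if (!num_ok(p$E) || p$E <= 0) bad(paste0("vessels.", v, ".E"), "must be > 0")
    if (!num_ok(p$V_d) || p$V_d < 0) bad(paste0("vessels.", v, ".V_d"), "must be >= 0")
  }
  for (v in names(bundle$circulation$valves)) {
    p <- bundle$circulation$valves[[v]]
    if (!num_ok(p$R) || p$R <= 0) {
      bad(paste0("circulation.valves.", v, ".R"), "must be > 0")
    }
    if (!is.null(p$L) && (!num_ok(p$L) || p$L <= 0)) {
      bad(paste0("circulation.valves.", v, ".L"), "must be > 0 when present")
    }
  }
  for (f in c("R_pul", "R_sys", "V_tot")) {
    if (!num_ok(bundle$circulation[[f]]) || bundle$circulation[[f]] <= 0) {
      bad(paste0("circulation.", f), "must be > 0")
    }
  }
  d <- bundle$driver
  if (d$N == 1) {
    if (abs(d$A[1] - 1) > 1e-12) bad("driver.A", "A[1] must be 1 when N = 1")
    if (abs(d$C_hat[1] - 0.5) > 1e-12) {
      bad("driver.C_hat", "C_hat[1] must be 0.5 when N = 1")
    }
    if (abs(d$C[1] - 30 / d$hr) > 1e-12) {
      bad("driver.C", "C[1] must be 30/HR (half a period) when N = 1")
    }
  }
  if (!num_ok(d$hr) || d$hr <= 0) bad("driver.hr", "must be > 0")
  if (!is.null(bundle$respiratory)) {
    r <- bundle$respiratory
    for (f in c("E_alv", "E_cw", "R_ua", "R_ca", "V_th0")) {
      if (!num_ok(r[[f]]) || r[[f]] <= 0) {
        bad(paste0("respiratory.", f), "must be > 0")
      }
    }
    if (!num_ok(r$beta) || r$beta < 0) bad("respiratory.beta", "must be >= 0")
    if (!num_ok(r$HB) || r$HB < 0) bad("respiratory.HB", "must be >= 0")
  }
  vols <- bundle$initial$volumes
  if (any(vols < 0)) {
    bad("initial.volumes", "all volumes must be >= 0")
  }
  if (abs(sum(vols) - bundle$circulation$V_tot) > 1e-12) {
    bad("initial.volumes",
        sprintf("volume sum %.15g must equal V_tot %.15g",
                sum(vols), bundle$circulation$V_tot))
  }
  tibble::tibble(field = field, rule = rule)
}
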