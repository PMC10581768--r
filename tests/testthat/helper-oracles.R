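# Independent oracles and shared (lazily computed, cached) simulations.

# Brute-force bisection root finder for the septum balance, independent of
# the package's Newton path. The residual is strictly decreasing, so the
# bracket [-V_rv, V_lv] always contains the unique root.
bisect_septum <- function(V_lv, V_rv, e, walls, tol = 1e-12) {
  f <- function(v) septum_residual(v, V_lv, V_rv, e, walls)
  lo <- -V_rv
  hi <- V_lv
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Heavy simulations shared across test files (helpers are sourced once per
# test run, so each runs at most once).
.sim_cache <- new.env()

cached_sim <- function(key, make) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- make()
  .sim_cache[[key]]
}

sim_noninertial_60 <- function() cached_sim("ni60", function() {
  simulate_cvs(cvr_preset("smith_noninertial"), t_end = 60)
})

sim_inertial_60 <- function() cached_sim("in60", function() {
  simulate_cvs(cvr_preset("smith_inertial"), t_end = 60)
})

sim_jallon_original_150 <- function() cached_sim("jo150", function() {
  simulate_cvs(cvr_preset("jallon"), t_end = 150, respiration = "original")
})

sim_jallon_stabilized_150 <- function() cached_sim("js150", function() {
  simulate_cvs(cvr_preset("jallon"), t_end = 150, respiration = "stabilized")
})

sim_hr_ramp_60 <- function() cached_sim("ramp60", function() {
  simulate_cvs(cvr_preset("smith_inertial"), t_end = 60,
               septum = "nonlinear", hr_profile = hr_tanh_ramp())
})
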