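test_that("the integrator reproduces analytic solutions at tolerance", {
  # linear decay
  sol <- cvrsim:::.integrate_dp45(function(t, y) -y, 1, seq(0, 5, 0.1),
                                  atol = 1e-9, rtol = 1e-7, max_steps = 1e5)
  expect_lt(max(abs(sol$y[, 1] - exp(-seq(0, 5, 0.1)))), 1e-6)
  # harmonic oscillator: phase and energy
  f <- function(t, y) c(y[2], -y[1])
  t <- seq(0, 20, 0.05)
  sol2 <- cvrsim:::.integrate_dp45(f, c(1, 0), t, 1e-9, 1e-8, 1e5)
  expect_lt(max(abs(sol2$y[, 1] - cos(t))), 1e-5)
  expect_lt(max(abs(rowSums(sol2$y^2) - 1)), 1e-5)
})

test_that("the integrator matches an independent stiff solver on a smooth system", {
  skip_if_not_installed("deSolve")
  # Van der Pol oscillator, mildly nonlinear
  f <- function(t, y) c(y[2], 2 * (1 - y[1]^2) * y[2] - y[1])
  t <- seq(0, 10, 0.1)
  mine <- cvrsim:::.integrate_dp45(f, c(2, 0), t, 1e-9, 1e-8, 1e6)
  ref <- deSolve::ode(y = c(2, 0), times = t,
                      func = function(t, y, p) list(f(t, y)), parms = NULL,
                      method = "lsoda", atol = 1e-11, rtol = 1e-10)
  expect_lt(max(abs(mine$y - ref[, 2:3])), 1e-5)
})

test_that("the error control localises a derivative discontinuity", {
  # flow-freeze analogue: y' = -1 while y > 0, else 0; exact floor at 0
  f <- function(t, y) if (y[1] > 0) -1 else 0
  sol <- cvrsim:::.integrate_dp45(f, 1, seq(0, 2, 0.1),
                                  atol = 1e-7, rtol = 1e-4, max_steps = 1e5)
  expect_gt(sol$y[nrow(sol$y), 1], -1e-4)
})

test_that("step budget exhaustion raises an error with the last state", {
  expect_error(simulate_cvs(cvr_preset("smith_noninertial"), t_end = 10,
                            max_steps = 50),
               "step budget.*last state")
})

test_that("invalid bundles are rejected before integration", {
  b <- cvr_preset("smith_noninertial")
  b$circulation$valves$av$R <- -2
  expect_error(simulate_cvs(b, t_end = 1), "invalid parameter bundle.*av.R")
  expect_error(simulate_cvs(cvr_preset("smith_noninertial"), t_end = 1,
                            respiration = "stabilized"),
               "no respiratory parameters")
})

test_that("total blood volume is conserved through a long simulation", {
  sim <- sim_noninertial_60()
  expect_lt(sim$meta$conservation_error, 1e-5)
  sim_i <- sim_inertial_60()
  expect_lt(sim_i$meta$conservation_error, 1e-4)
})

test_that("non-inertial valve flows are never negative on the output grid", {
  ts <- sim_noninertial_60()$timeseries
  expect_true(all(ts$Q_mt >= 0 & ts$Q_av >= 0 & ts$Q_tc >= 0 & ts$Q_pv >= 0))
})

test_that("warm-started Newton stays within a few iterations per solve", {
  m <- sim_noninertial_60()$meta$newton
  expect_lt(m$total_iterations / m$evals, 3)
  expect_lte(m$max_iterations, 21)
  expect_lt(m$bisection_fallbacks / m$evals, 0.02)
})

test_that("spurious inertial backflow shrinks with the absolute tolerance", {
  loose <- simulate_cvs(cvr_preset("smith_inertial"), t_end = 20,
                        atol = 1e-5)$meta$min_valve_flow
  tight <- simulate_cvs(cvr_preset("smith_inertial"), t_end = 20,
                        atol = 1e-7)$meta$min_valve_flow
  expect_lt(tight, 0)
  ratio <- abs(loose) / abs(tight)
  expect_gt(ratio, 10)
  expect_lt(ratio, 1e4)
})

test_that("halving the relative tolerance barely changes a settled beat", {
  s1 <- simulate_cvs(cvr_preset("smith_noninertial"), t_end = 10,
                     rtol = 1e-4)
  s2 <- simulate_cvs(cvr_preset("smith_noninertial"), t_end = 10,
                     rtol = 5e-5)
  i <- s1$timeseries$t >= 9 & s1$timeseries$t <= 9.75
  rms <- sqrt(mean((s1$timeseries$P_ao[i] - s2$timeseries$P_ao[i])^2))
  expect_lt(rms, 0.1)
})

test_that("variable-rate mode with a constant profile reproduces constant mode", {
  # at tight tolerance the two formulations converge to the same trajectory
  b <- cvr_preset("smith_noninertial")
  bc <- b
  bc$driver <- driver_config(B = 80 * (80 / 60)^2, hr = 80)
  s_c <- simulate_cvs(bc, t_end = 5, atol = 1e-10, rtol = 1e-7)
  s_v <- simulate_cvs(b, t_end = 5, atol = 1e-10, rtol = 1e-7,
                      hr_profile = hr_constant(80))
  vols <- c("V_pa", "V_pu", "V_lv", "V_ao", "V_vc", "V_rv")
  d <- max(abs(as.matrix(s_c$timeseries[vols]) -
                 as.matrix(s_v$timeseries[vols])))
  expect_lt(d, 1e-4)
})

test_that("beats are segmented analytically at constant rate", {
  sim <- sim_noninertial_60()
  beats <- extract_beats(sim)
  expect_identical(nrow(beats), 80L)  # 60 s at 80 min^-1
  expect_equal(beats$t_start, (0:79) * 0.75)
  expect_true(all(beats$P_ao_sys >= beats$P_ao_dia))
  expect_true(all(beats$SV_lv >= 0 & beats$SV_rv >= 0))
  expect_equal(beats$hr_mean, rep(80, 80))
})

test_that("beats follow integer phase crossings at variable rate", {
  sim <- sim_hr_ramp_60()
  beats <- extract_beats(sim)
  expect_identical(nrow(beats), 86L)  # floor of the integrated cycle count
  expect_true(all(diff(beats$t_start) > 0))
  # per-beat mean rate climbs monotonically along the ramp
  expect_true(all(diff(beats$hr_mean) > -1e-6))
  expect_equal(beats$hr_mean[1], 60, tolerance = 0.01)
  expect_equal(beats$hr_mean[86], 100, tolerance = 0.01)
})

test_that("too short a run yields an empty beat table with a warning", {
  sim <- simulate_cvs(cvr_preset("smith_noninertial"), t_end = 1)
  expect_warning(beats <- extract_beats(sim), "fewer than 2")
  expect_identical(nrow(beats), 0L)
})

test_that("drift statistic requires enough breaths", {
  sim <- simulate_cvs(cvr_preset("jallon"), t_end = 12)
  expect_error(drift_statistic(sim), "at least 5")
})

test_that("time series files round-trip bit-exactly", {
  sim <- simulate_cvs(cvr_preset("smith_noninertial"), t_end = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(sim, path)
  ts2 <- read_timeseries(path)
  expect_identical(names(ts2), names(sim$timeseries))
  for (col in names(ts2)) expect_identical(ts2[[col]], sim$timeseries[[col]])
})

test_that("metrics reports round-trip through the reader", {
  sim <- sim_jallon_stabilized_150()
  path <- withr::local_tempfile(fileext = ".txt")
  write_metrics(sim, path)
  m <- read_metrics(path)
  expect_identical(m$meta[["preset"]], "jallon")
  expect_identical(m$meta[["respiration"]], "stabilized")
  beats <- extract_beats(sim)
  expect_equal(as.data.frame(m$beats), as.data.frame(beats),
               tolerance = 1e-12)
  expect_equal(as.data.frame(m$breaths),
               as.data.frame(extract_breaths(sim)), tolerance = 1e-12)
})

test_that("tidy and glance summarise a simulation", {
  sim <- simulate_cvs(cvr_preset("smith_noninertial"), t_end = 2)
  long <- tidy(sim, signals = c("P_ao", "V_lv"))
  expect_identical(names(long), c("t", "signal", "value"))
  expect_identical(sort(unique(long$signal)), c("P_ao", "V_lv"))
  g <- glance(sim)
  expect_identical(nrow(g), 1L)
  expect_identical(g$preset, "smith_noninertial")
  expect_true(g$conservation_error < 1e-5)
})

test_that("plot constructors return ggplot objects", {
  sim <- simulate_cvs(cvr_preset("smith_noninertial"), t_end = 2)
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
  expect_s3_class(plot_pv_loop(sim, "lv", t_range = c(1, 2)), "ggplot")
})

test_that("all four model variants complete a short horizon", {
  expect_s3_class(simulate_cvs(cvr_preset("smith_noninertial"), t_end = 2,
                               septum = "linearized"), "cvr_sim")
  expect_s3_class(simulate_cvs(cvr_preset("smith_inertial"), t_end = 2),
                  "cvr_sim")
  expect_s3_class(simulate_cvs(cvr_preset("jallon"), t_end = 2,
                               septum = "nonlinear"), "cvr_sim")
  expect_s3_class(simulate_cvs(cvr_preset("smith_noninertial"), t_end = 2,
                               hr_profile = hr_sampled(
                                 hr_trace_fixture("random_walk", seed = 2))),
                  "cvr_sim")
})
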