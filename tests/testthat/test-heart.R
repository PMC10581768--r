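walls_ni <- cvr_preset("smith_noninertial")$walls
walls_in <- cvr_preset("smith_inertial")$walls

# identical free walls, septum with no dead-space/zero-pressure offset:
# the septum balance is then symmetric and the root is exactly zero
walls_sym <- list(
  lvf = chamber_params(E_es = 1000, V_d = 0.005, V_0 = 0.005,
                       lam = 20, P_0 = 0.8),
  rvf = chamber_params(E_es = 1000, V_d = 0.005, V_0 = 0.005,
                       lam = 20, P_0 = 0.8),
  spt = chamber_params(E_es = 40000, V_d = 0, V_0 = 0, lam = 400, P_0 = 1),
  pcd = chamber_params(V_0 = 0.2, lam = 30, P_0 = 0.5003)
)

test_that("end-systolic law is linear about the dead-space volume", {
  p <- walls_in$lvf
  expect_equal(espvr_pressure(p$V_d, p), 0)
  expect_equal(espvr_pressure(0.1375, p), 2879.8 * 0.1375)
  expect_equal(espvr_pressure(0.1375, p), 395.97, tolerance = 1e-4)
  p2 <- chamber_params(E_es = 100, V_d = 0.01, V_0 = 0.01, lam = 1, P_0 = 1)
  expect_equal(espvr_pressure(2 * p2$V_d, p2), -espvr_pressure(0, p2))
})

test_that("end-diastolic law is exponential about the zero-pressure volume", {
  p <- walls_ni$lvf
  expect_equal(edpvr_pressure(p$V_0, p), 0)
  expect_equal(edpvr_pressure(p$V_0 + 1 / p$lam, p), p$P_0 * (exp(1) - 1))
  V <- seq(0.01, 0.3, length.out = 50)
  expect_true(all(diff(edpvr_pressure(V, p)) > 0))
})

test_that("linearised EDPVR is the first-order expansion", {
  p <- walls_ni$spt
  expect_equal(edpvr_linear(p$V_0, p), 0)
  expect_equal(edpvr_linear(p$V_0 + 1 / p$lam, p), p$P_0)
  # Taylor remainder: |nonlinear - linear| / (V - V_0)^2 stays bounded by
  # (and converges to) P_0 lam^2 / 2 as V -> V_0
  lim <- p$P_0 * p$lam^2 / 2
  for (dV in 10^seq(-4, -7)) {
    r <- abs(edpvr_pressure(p$V_0 + dV, p) - edpvr_linear(p$V_0 + dV, p)) / dV^2
    expect_lt(r, 2 * lim)
  }
  r_small <- abs(edpvr_pressure(p$V_0 + 1e-7, p) -
                   edpvr_linear(p$V_0 + 1e-7, p)) / 1e-14
  expect_equal(r_small, lim, tolerance = 1e-4)
})

test_that("wall pressure blends the two laws through the activation", {
  p <- walls_ni$rvf
  V <- 0.11
  expect_equal(wall_pressure(V, 1, p), espvr_pressure(V, p))
  expect_equal(wall_pressure(V, 0, p), edpvr_pressure(V, p))
  expect_equal(wall_pressure(V, 0.5, p),
               (espvr_pressure(V, p) + edpvr_pressure(V, p)) / 2)
  # passive pericardium ignores the activation
  expect_equal(wall_pressure(0.25, 0.7, walls_ni$pcd),
               edpvr_pressure(0.25, walls_ni$pcd))
})

test_that("septum residual vanishes by symmetry and decreases in V_spt", {
  expect_equal(septum_residual(0, 0.1, 0.1, 0.5, walls_sym), 0)
  v <- seq(-0.01, 0.01, length.out = 41)
  for (e in c(0, 0.5, 1)) {
    f <- septum_residual(v, 0.1375, 0.132, e, walls_ni)
    expect_true(all(diff(f) < 0))
    expect_identical(sum(diff(sign(f)) != 0), 1L)  # exactly one sign change
  }
})

test_that("Newton septum solve matches the bisection oracle", {
  expect_equal(as.numeric(solve_septum(0.1, 0.1, 0.5, walls_sym, guess = 0.004)),
               0, tolerance = 1e-12)
  v_n <- as.numeric(solve_septum(0.1375, 0.132, 0, walls_ni, guess = 0))
  v_b <- bisect_septum(0.1375, 0.132, 0, walls_ni)
  expect_lt(abs(v_n - v_b), 1e-9)
  expect_lt(abs(septum_residual(v_n, 0.1375, 0.132, 0, walls_ni)), 1e-9)

  set.seed(7)
  for (i in 1:100) {
    V_lv <- runif(1, 0.05, 0.2)
    V_rv <- runif(1, 0.05, 0.2)
    e <- runif(1)
    w <- if (i %% 2 == 0) walls_ni else walls_in
    v_n <- as.numeric(solve_septum(V_lv, V_rv, e, w, guess = 0))
    expect_lt(abs(v_n - bisect_septum(V_lv, V_rv, e, w)), 1e-9)
  }
})

test_that("closed-form linearised solve zeroes the fully-linearised residual", {
  lin_residual <- function(v, V_lv, V_rv, e, w) {
    p_lin <- function(V, e, p) {
      if (is.null(p$E_es)) return(edpvr_linear(V, p))
      e * espvr_pressure(V, p) + (1 - e) * edpvr_linear(V, p)
    }
    p_lin(V_lv - v, e, w$lvf) - p_lin(V_rv + v, e, w$rvf) - p_lin(v, e, w$spt)
  }
  expect_equal(solve_septum_linearized(0.1, 0.1, 0.5, walls_sym), 0)
  set.seed(11)
  for (i in 1:50) {
    V_lv <- runif(1, 0.05, 0.2)
    V_rv <- runif(1, 0.05, 0.2)
    e <- runif(1)
    v <- solve_septum_linearized(V_lv, V_rv, e, walls_ni)
    expect_lt(abs(lin_residual(v, V_lv, V_rv, e, walls_ni)), 1e-10)
  }
  # full systole with zero free-wall dead space: diastolic terms drop out
  w <- walls_in
  v1 <- solve_septum_linearized(0.14, 0.13, 1, w)
  expect_equal(v1, (w$lvf$E_es * 0.14 - w$rvf$E_es * 0.13 +
                      w$spt$E_es * w$spt$V_d) /
                 (w$lvf$E_es + w$rvf$E_es + w$spt$E_es))
})

test_that("nonlinear and linearised septum agree in the small-deflection limit", {
  # all three walls within 1e-3 l of their zero-pressure volumes
  V_lv <- walls_ni$lvf$V_0 + 8e-4
  V_rv <- walls_ni$rvf$V_0 + 6e-4
  for (e in c(0, 0.3, 0.8)) {
    v_n <- as.numeric(solve_septum(V_lv, V_rv, e, walls_ni, guess = 0))
    v_l <- solve_septum_linearized(V_lv, V_rv, e, walls_ni)
    expect_lt(abs(v_n - v_l), 0.01 * V_lv)
  }
})

test_that("chamber pressures satisfy the interaction identities", {
  hp <- heart_pressures(0.1375, 0.132, 0.4, -4, walls_ni, mode = "nonlinear",
                        guess = 0)
  # septal pressure equals the free-wall pressure difference at the root
  expect_lt(abs(wall_pressure(hp$V_spt, 0.4, walls_ni$spt) -
                  (wall_pressure(hp$V_lvf, 0.4, walls_ni$lvf) -
                     wall_pressure(hp$V_rvf, 0.4, walls_ni$rvf))), 1e-9)
  expect_equal(hp$V_pcd, 0.1375 + 0.132)
  expect_equal(hp$V_lvf + hp$V_rvf, hp$V_pcd)
  expect_equal(hp$P_peri,
               edpvr_pressure(hp$V_pcd, walls_ni$pcd) - 4)

  # symmetric construction: equal ventricles see equal pressures
  hps <- heart_pressures(0.1, 0.1, 0, -4, walls_sym, mode = "nonlinear",
                         guess = 0)
  expect_equal(hps$P_lv, hps$P_rv)

  # linearised mode still reports full nonlinear wall pressures
  hpl <- heart_pressures(0.1375, 0.132, 0.4, -4, walls_ni,
                         mode = "linearized")
  expect_equal(hpl$P_lv,
               wall_pressure(0.1375 - hpl$V_spt, 0.4, walls_ni$lvf) +
                 edpvr_pressure(0.2695, walls_ni$pcd) - 4)
})

test_that("septum solver recovers from a stale warm start", {
  v <- solve_septum(0.1375, 0.132, 0.5, walls_ni, guess = 25)
  expect_lt(abs(as.numeric(v) - bisect_septum(0.1375, 0.132, 0.5, walls_ni)),
            1e-9)
})

test_that("wall pressure slope is positive for every compartment law", {
  # the uniqueness premise of the septum balance
  dV <- 1e-7
  for (w in list(walls_ni$lvf, walls_ni$rvf, walls_ni$spt, walls_in$lvf)) {
    for (e in c(0, 0.5, 1)) {
      for (V in seq(0.02, 0.25, length.out = 10)) {
        slope <- (wall_pressure(V + dV, e, w) - wall_pressure(V, e, w)) / dV
        expect_gt(slope, 0)
      }
    }
  }
})
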