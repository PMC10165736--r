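test_that("controller tracks, saturates at the resting pool, and deactivates", {
  expect_equal(ccr_controller(ccr_state(0, 100, 0), 50), 50)
  expect_equal(ccr_controller(ccr_state(0, 30, 70), 50), 30)
  expect_equal(ccr_controller(ccr_state(80, 20, 0), 50), -30)
  expect_equal(ccr_controller(ccr_state(50, 50, 0), 50), 0)
})

test_that("compartment derivatives conserve the motor-unit pool", {
  p <- fatigue_params(0.02, 0.01, 10)
  # rested, no demand: equilibrium
  d <- ccr_derivatives(ccr_state(), 0, p)
  expect_equal(unlist(d), c(dMa = 0, dMr = 0, dMf = 0))
  # fully active at maximal demand: fatigue flow F * Ma
  d <- ccr_derivatives(ccr_state(100, 0, 0), 100, fatigue_params(0.004, 0.01))
  expect_equal(d$dMf, 0.4)
  # conservation on random valid states
  set.seed(42)
  for (i in 1:50) {
    x <- runif(3); x <- 100 * x / sum(x)
    tl <- runif(1, 0, 100)
    d <- ccr_derivatives(ccr_state(x[1], x[2], x[3]), tl, p)
    expect_equal(d$dMa + d$dMr + d$dMf, 0)
  }
})

test_that("RK4 stepping conserves the pool and is self-consistent in dt", {
  p <- fatigue_params(0.01, 0.005, 15)
  s <- ccr_state()
  expect_equal(ccr_step(s, 0, p, 0.5), s)   # rested, no demand

  s <- ccr_state(40, 35, 25)
  s1 <- ccr_step(s, 60, p, 0.5)
  expect_equal(s1$Ma + s1$Mr + s1$Mf, 100, tolerance = 1e-9)

  # one step at dt vs two at dt/2, smooth branch (ample resting pool)
  big <- ccr_step(ccr_state(10, 80, 10), 70, p, 0.01)
  small <- ccr_step(ccr_step(ccr_state(10, 80, 10), 70, p, 0.005), 70, p, 0.005)
  expect_equal(big$Ma, small$Ma, tolerance = 1e-10)
  expect_equal(big$Mf, small$Mf, tolerance = 1e-12)
})

test_that("trajectories conserve the pool and track constant target loads", {
  p <- fatigue_params(0.004, 0.01)
  traj <- ccr_simulate(100, p, duration = 100, dt = 0.01)  # 1e4 steps
  expect_true(all(abs(traj$Ma + traj$Mr + traj$Mf - 100) < 1e-6))

  # zero demand from rest: nothing happens
  traj0 <- ccr_simulate(0, fatigue_params(0.01, 0.01, 10), 10, dt = 0.05)
  expect_true(all(traj0$Mf == 0) && all(traj0$Mr == 100))

  # tracking: |Ma - TL| decreases monotonically to the controller's
  # steady-state offset TL*F/(1+F)
  p <- fatigue_params(0.004, 0.01)
  traj <- ccr_simulate(25, p, 40, dt = 0.01)
  err <- abs(traj$Ma - 25)
  expect_true(all(diff(err) < 1e-12))
  expect_lt(tail(err, 1), 0.1)
})

test_that("rest recovery multiplier accelerates recovery only at rest", {
  fast <- fatigue_params(0.01, 0.005, r_rest = 15)
  slow <- fatigue_params(0.01, 0.005, r_rest = 1)
  init <- ccr_state(0, 60, 40)
  tf <- ccr_simulate(0, fast, 60, dt = 0.05, init = init)
  ts <- ccr_simulate(0, slow, 60, dt = 0.05, init = init)
  expect_true(all(tf$Mf[-1] < ts$Mf[-1]))
})

test_that("endurance time is monotone in load, fatigue and recovery rates", {
  endurance <- function(tl, F, R) {
    traj <- ccr_simulate(tl, fatigue_params(F, R), 2000, dt = 0.1)
    idx <- which(100 - traj$Mf < tl)
    if (length(idx)) traj$t_s[idx[1]] else Inf
  }
  base <- endurance(60, 0.01, 0.005)
  expect_lte(endurance(80, 0.01, 0.005), base)   # heavier load fails sooner
  expect_lte(endurance(60, 0.02, 0.005), base)   # faster fatigue fails sooner
  expect_gte(endurance(60, 0.01, 0.01), base)    # faster recovery lasts longer
})

test_that("long maximal effort converges to the closed-form endurance asymptote", {
  expect_equal(endurance_asymptote(fatigue_params(0.01, 0.01)), 50)
  p <- fatigue_params(0.004, 0.01)
  expect_equal(endurance_asymptote(p), 100 / (0.004 / 0.01 + 1))
  traj <- ccr_simulate(100, p, duration = 10 / p$R, dt = 0.05)
  final <- residual_capacity(ccr_state(tail(traj$Ma, 1), tail(traj$Mr, 1),
                                       tail(traj$Mf, 1)))
  expect_lt(abs(final - endurance_asymptote(p)), 0.5)
})

test_that("residual capacity is the non-fatigued share", {
  expect_equal(residual_capacity(ccr_state(0, 100, 0)), 100)
  s <- ccr_state(40, 36.7, 23.3)
  expect_equal(residual_capacity(s), 76.7)
  expect_equal(residual_capacity(s), s$Ma + s$Mr)
})

test_that("fatigue scales the contractile force ceiling but not the passive force", {
  m <- list(name = "m", l0M = 0.1, lST = 0.2, alpha0 = 0, F0M = 500)
  fs <- fiber_state_rigid_tendon(m, lMT = 0.3)
  expect_equal(fatigued_force_ceiling(m, fs, 0), force_bounds(m, fs)$f_max)
  expect_equal(fatigued_force_ceiling(m, fs, 100), 0)
  expect_equal(fatigued_force_ceiling(m, fs, 50), 250)
  # stretched: passive floor survives full fatigue
  fs <- fiber_state_rigid_tendon(m, lMT = 0.325)
  expect_equal(fatigued_force_ceiling(m, fs, 100),
               force_bounds(m, fs)$f_min)
})
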