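test_that("zero demand on a rested model leaves forces passive and fatigue untouched", {
  m <- simple_elbow_model()
  states <- fatiguesim:::session_states(m)
  step <- run_timestep(m, states, list(phi = 50, phidot = 0, Q = 0))
  expect_equal(step$solution$forces, c(0, 0))      # no passive force at optimum
  expect_equal(step$tl, c(0, 0))
  expect_equal(step$states$Mf, c(0, 0))
  expect_equal(step$states$Mr, c(100, 100))
})

test_that("constant submaximal demand produces compensatory activation growth", {
  m <- simple_elbow_model(F = 0.05, R = 0.005)   # fast-fatiguing for a short test
  states <- fatiguesim:::session_states(m)
  sample <- list(phi = 50, phidot = 0, Q = 7)
  acts <- numeric(200)
  for (k in 1:200) {
    step <- run_timestep(m, states, sample, dt = 0.05)
    states <- step$states
    acts[k] <- step$solution$activations[1]
  }
  expect_gt(acts[200], acts[50])
  expect_gt(acts[50], acts[10])
})

test_that("single-muscle target load follows the fatigued-capacity closed form", {
  m <- simple_elbow_model(F0M_ext = 1)   # negligible antagonist
  states <- fatiguesim:::session_states(m)
  Q <- 6; J <- 0.03
  sample <- list(phi = 50, phidot = 0, Q = Q)
  for (k in 1:100) {
    prev_Mf <- states$Mf[1]
    step <- run_timestep(m, states, sample, dt = 0.05)
    # at the optimum posture: a = Q / (J * F0M * (100 - Mf)/100)
    expect_equal(step$tl[1],
                 100 * Q / (J * 500 * (100 - prev_Mf) / 100),
                 tolerance = 1e-6)
    states <- step$states
  }
})

test_that("available moment matches the rested bounds and halves at 50% fatigue", {
  m <- simple_elbow_model()
  ctx <- fatiguesim:::session_context(m)
  rested <- available_max_moment(m, 50)
  expect_equal(rested, 0.03 * 500)   # fl = fv = 1, no extensor passive moment
  expect_equal(available_max_moment(m, 50, Mf = c(50, 0)), rested / 2)
  # monotone: more fatigue never increases the available moment
  vals <- sapply(seq(0, 100, 10),
                 function(mf) available_max_moment(m, 50, Mf = c(mf, 0)))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("failure prediction agrees with a direct compartment-model oracle", {
  m <- simple_elbow_model(F0M_ext = 1, F = 0.02, R = 0.005)
  Q <- 9; J <- 0.03; F0 <- 500
  tl0 <- 100 * Q / (J * F0)      # demand in % of rested capacity
  dt <- 0.05
  pf <- predict_failure_time(m, Q, 50, dt = dt, horizon = 300)

  # independent oracle: scalar 3CCr with state-dependent TL (percent of
  # remaining capacity), forward-Euler at a finer step
  oracle <- local({
    Ma <- 0; Mr <- 100; Mf <- 0; F <- 0.02; R <- 0.005; h <- 0.005
    t <- 0
    repeat {
      if (100 - Mf < tl0) break
      tl <- 100 * tl0 / (100 - Mf)
      d <- tl - Ma
      C <- if (d > 0) min(d, Mr) else d
      dMa <- C - F * Ma; dMf <- F * Ma - R * Mf; dMr <- -C + R * Mf
      Ma <- Ma + h * dMa; Mr <- Mr + h * dMr; Mf <- Mf + h * dMf
      t <- t + h
      if (t > 400) break
    }
    t
  })
  expect_false(pf$censored)
  expect_lt(abs(pf$failure_time_s - oracle), dt + 0.05)

  # boundary and monotonicity properties
  over <- predict_failure_time(m, available_max_moment(m, 50) * 1.01, 50,
                               dt = dt, horizon = 10)
  expect_equal(over$failure_time_s, 0)
  m_slow <- simple_elbow_model(F0M_ext = 1, F = 0.01, R = 0.005)
  pf_slow <- predict_failure_time(m_slow, Q, 50, dt = dt, horizon = 600)
  expect_gt(pf_slow$failure_time_s, pf$failure_time_s)
})

test_that("a vanishing fatigue rate reproduces pure static optimization", {
  m <- simple_elbow_model(F = 1e-10, R = 1e-10, r_rest = 1)
  subj <- list(forearm_mass_kg = 1.5, forearm_com_m = 0.13,
               forearm_inertia_kgm2 = 0.01, forearm_length_m = 0.3)
  prot <- protocol(list(
    list(kind = "curl_set", reps = 2, cadence_s = 3, mass_kg = 4)
  ), subject = subj)
  res <- simulate_protocol(m, prot, dt = 0.05)
  motion <- generate_curl_motion(2, 3, c(30, 130), subj, mass_kg = 4,
                                 dt = 0.05)
  rested <- fatiguesim:::session_states(m)
  for (row in c(10, 60, 110)) {
    mo <- motion[row + 1, ]    # session drops the duplicated t = 0 sample
    static <- run_timestep(m, rested,
                           list(phi = mo$phi_deg, phidot = mo$phidot_deg_s,
                                Q = mo$Q_Nm), dt = 0.05)
    expect_equal(res$forces_N[row, ], static$solution$forces,
                 tolerance = 1e-6)
  }
})

test_that("aggregated 2M session matches the summed 7M session for identical flexors", {
  m7 <- simple_elbow_model(F0M_flex = c(300, 300), n_flexors = 2)
  m2 <- aggregate_to_joint_actuators(m7)
  subj <- list(forearm_mass_kg = 1.5, forearm_com_m = 0.13,
               forearm_inertia_kgm2 = 0.01, forearm_length_m = 0.3)
  prot <- protocol(list(
    list(kind = "static_hold", duration_s = 5, phi_deg = 50, Q_Nm = 8)
  ), subject = subj)
  r7 <- simulate_protocol(m7, prot, dt = 0.05)
  r2 <- simulate_protocol(m2, prot, dt = 0.05)
  flex7 <- which(m7$muscles$role == "flexor")
  flex2 <- which(m2$muscles$role == "flexor")
  expect_equal(rowSums(r7$forces_N[, flex7]), r2$forces_N[, flex2],
               tolerance = 1e-6)
  expect_equal(r7$Mf[, flex7[1]], r2$Mf[, flex2], tolerance = 1e-6)
})

test_that("14M sessions recruit group A to saturation before group B", {
  m <- make_toy_elbow_model(seed = 4)
  m14 <- split_fiber_types(m, pct_decay = 25)
  # demand high enough that group B must engage
  Q <- 0.8 * available_max_moment(m14, 50)
  prot <- protocol(list(
    list(kind = "static_hold", duration_s = 10, phi_deg = 50, Q_Nm = Q)
  ))
  res <- simulate_protocol(m14, prot, dt = 0.05,
                           criterion = "fatigue-weighted")
  gA <- grep("_A$", res$muscles)
  gB <- grep("_B$", res$muscles)
  base <- sub("_B$", "", res$muscles[gB])
  for (row in seq(5, nrow(res$timeseries), by = 20)) {
    for (j in seq_along(gB)) {
      if (!is.na(res$activations[row, gB[j]]) &&
          res$activations[row, gB[j]] > 0.01) {
        a_partner <- res$activations[row, match(paste0(base[j], "_A"),
                                                res$muscles)]
        expect_gte(a_partner, 0.99)
      }
    }
  }
  expect_gt(max(res$activations[, gB], na.rm = TRUE), 0.01)  # B did engage
})

test_that("protocol segments execute in order with rest recovery and MVC decay", {
  m <- simple_elbow_model()
  # a rest-only protocol keeps the rested state rested
  r0 <- simulate_protocol(m, protocol(list(list(kind = "rest",
                                                duration_s = 5,
                                                phi_deg = 50))), dt = 0.05)
  expect_true(all(r0$Mr == 100))
  # and a fatigued state relaxes toward Mr = 100 under the rest multiplier
  res <- ccr_simulate(0, fatigue_params(0.01, 0.005, 15), 120, dt = 0.05,
                      init = ccr_state(0, 60, 40))
  expect_gt(tail(res$Mr, 1), 95)

  # MVC segments record a non-increasing available moment
  prot <- protocol(list(list(kind = "mvc", duration_s = 8, phi_deg = 50)))
  r <- simulate_protocol(m, prot, dt = 0.05)
  avail <- r$timeseries$available_Nm
  expect_true(all(diff(avail) <= 1e-9))
  expect_equal(avail[1], available_max_moment(m, 50), tolerance = 1e-3)
})

test_that("repeated work-rest cycles either reach equilibrium or fatigue monotonically", {
  subj <- list(forearm_mass_kg = 1.5, forearm_com_m = 0.13,
               forearm_inertia_kgm2 = 0.01, forearm_length_m = 0.3)
  make_prot <- function(hold_Q, rest_s, n_cycles) {
    segs <- list()
    for (cy in seq_len(n_cycles)) {
      segs <- c(segs, list(
        list(kind = "static_hold", duration_s = 10, phi_deg = 50,
             Q_Nm = hold_Q),
        list(kind = "rest", duration_s = rest_s, phi_deg = 50, cycle = cy)
      ))
    }
    protocol(segs, subject = subj)
  }
  m <- simple_elbow_model()
  # light work, long rests: recovery balances fatigue -> equilibrium
  res_eq <- simulate_protocol(m, make_prot(3, 60, 8), dt = 0.05)
  # heavy work, hardly any rest: fatigue accumulates monotonically
  res_grow <- simulate_protocol(m, make_prot(12, 5, 8), dt = 0.05)
  expect_true(isTRUE(res_eq$events$equilibrium))
  expect_false(isTRUE(res_grow$events$equilibrium))
  flex_idx <- which(m$muscles$role == "flexor")[1]
  seg_ends <- cumsum(rle(res_grow$timeseries$segment)$lengths)
  rest_ends <- seg_ends[seq(2, length(seg_ends), by = 2)]   # end of each rest
  ends_grow <- res_grow$Mf[rest_ends, flex_idx]
  expect_true(all(diff(ends_grow) > 0))   # strictly growing cycle fatigue
})

test_that("MVC comparison metrics recover known offsets and window identities", {
  t <- seq(0, 10, 0.01)
  meas <- data.frame(t_s = t, Q_Nm = 50 + 5 * sin(t))
  sim <- meas
  cmp <- compare_mvc(sim, meas)
  expect_equal(cmp$rmse_Nm, 0)
  expect_equal(cmp$first_peak_error_Nm, 0)

  sim$Q_Nm <- meas$Q_Nm + 2
  cmp <- compare_mvc(sim, meas, windows = list(c(0, 4), c(4, 10)))
  expect_equal(cmp$rmse_Nm, c(2, 2))
  expect_equal(cmp$first_peak_error_Nm, 2)

  # whole-trace MSE decomposes into window MSEs weighted by sample counts
  set.seed(3)
  sim$Q_Nm <- meas$Q_Nm + rnorm(length(t), 0, 1)
  w <- list(c(0, 5), c(5.01, 10))
  cmp_w <- compare_mvc(sim, meas, w)
  cmp_all <- compare_mvc(sim, meas)
  n1 <- sum(t >= 0 & t <= 5); n2 <- sum(t >= 5.01 & t <= 10)
  mse <- (n1 * cmp_w$rmse_Nm[1]^2 + n2 * cmp_w$rmse_Nm[2]^2) / (n1 + n2)
  expect_equal(sqrt(mse), cmp_all$rmse_Nm, tolerance = 1e-9)
  expect_error(compare_mvc(sim, meas, windows = list(c(20, 30))), "empty")
})
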