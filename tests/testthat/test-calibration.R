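test_that("actuator F0 extraction inverts the maximal-moment relation", {
  expect_equal(estimate_actuator_F0(60, 0.03, 1), 2000)
  expect_equal(estimate_actuator_F0(60, 0.06, 1), 1000)   # doubling J halves F0
  expect_equal(estimate_actuator_F0(60, 0.03, method = "static"), 2000)
  expect_error(estimate_actuator_F0(60, 0.03, 0), "physiological factor")
  expect_error(estimate_actuator_F0(60, -0.01, 1), "moment arm")
})

test_that("estimate summaries agree with a two-pass oracle and handle ties", {
  set.seed(9)
  x <- runif(8, 1000, 2000)
  s <- summarize_estimates(x)
  mu <- sum(x) / length(x)
  expect_equal(s$mean, mu, tolerance = 1e-9)
  expect_equal(s$sd, sqrt(sum((x - mu)^2) / (length(x) - 1)), tolerance = 1e-9)
  expect_equal(summarize_estimates(c(5, 5, 5))$sd, 0)
  expect_error(summarize_estimates(1500), "two")
})

test_that("moment-arm calibration recovers an injected distortion and reduces spread", {
  m <- make_toy_elbow_model(seed = 3)
  postures <- data.frame(phi_deg = rep(c(15, 30, 45, 60), each = 2))
  act <- fatiguesim:::actuator_at_postures(m, postures$phi_deg)
  F0_true <- 1800
  postures$Qmax_Nm <- F0_true * act$J_flex * act$phys_factor + act$Q_ext_passive

  # consistent data: identity is optimal and spread stays ~0
  cal0 <- calibrate_moment_arm_scale(postures, m)
  expect_equal(cal0$k1, 1, tolerance = 1e-3)
  expect_lt(cal0$post$sd, 1e-3)

  # distort the moment-arm variation by a known factor, then recover 1/c
  for (c_dist in c(0.7, 1.3)) {
    md <- m
    for (nm in md$muscles$name) {
      g <- md$geometry[[nm]]
      J0 <- splinefun(g$phi_deg, g$moment_arm_m, method = "natural")(0)
      md$geometry[[nm]]$moment_arm_m <- c_dist * (g$moment_arm_m - J0) + J0
    }
    cal <- calibrate_moment_arm_scale(postures, md)
    expect_equal(cal$k1, 1 / c_dist, tolerance = 0.01)
    expect_lte(cal$post$sd, cal$pre$sd)
    expect_lt(cal$post$sd, cal$pre$sd / 5)   # near-total spread removal here
  }
})

test_that("F0 scaling matches the strongest measured instant and is idempotent", {
  m <- simple_elbow_model()
  cap <- available_max_moment(m, 50)
  tr <- data.frame(t_s = seq(0, 2, 0.1), Q_Nm = cap)
  cal <- calibrate_F0_scale(tr, m, phi_deg = 50)
  expect_equal(cal$k2, 1, tolerance = 1e-9)
  expect_equal(cal$model$muscles$F0M, m$muscles$F0M)

  tr$Q_Nm <- 1.2 * cap
  cal <- calibrate_F0_scale(tr, m, phi_deg = 50)
  expect_equal(cal$k2, 1.2, tolerance = 1e-9)
  expect_equal(cal$model$muscles$F0M, 1.2 * m$muscles$F0M)

  # recomputing k2 on the scaled model yields max k2 = 1
  cal2 <- calibrate_F0_scale(tr, cal$model, phi_deg = 50)
  expect_equal(cal2$k2, 1, tolerance = 1e-6)
})

test_that("fatigue-parameter fitting recovers the generating parameters", {
  subj <- synthetic_subject(seed = 1)
  pair <- generate_mvc_pair(subj, decay_s = 60, rest_s = 15, probe_s = 6,
                            fs = 20)
  fit <- fit_fatigue_parameters(pair$decay, pair$probe)
  truth <- subj$fatigue_true
  expect_lt(abs(fit$params$F - truth$F) / truth$F, 0.05)
  expect_lt(abs(fit$params$R - truth$R) / truth$R, 0.05)
  expect_lt(abs(fit$params$r_rest - truth$r_rest) / truth$r_rest, 0.05)
  # noise-free self-consistency: residual far below the trace norm
  trace_norm <- sqrt(sum(pair$decay$force_norm^2) +
                       sum(pair$probe$force_norm^2))
  expect_lt(fit$residual_norm, 1e-5 * trace_norm)
})

test_that("noisy traces still identify the fatigue parameters to within 15%", {
  subj <- synthetic_subject(seed = 1)
  pair <- generate_mvc_pair(subj, decay_s = 60, rest_s = 15, probe_s = 6,
                            noise_sd_pct = 2, seed = 7, fs = 20)
  fit <- fit_fatigue_parameters(pair$decay, pair$probe)
  truth <- subj$fatigue_true
  expect_lt(abs(fit$params$F - truth$F) / truth$F, 0.15)
  expect_lt(abs(fit$params$R - truth$R) / truth$R, 0.15)
  expect_lt(abs(fit$params$r_rest - truth$r_rest) / truth$r_rest, 0.15)
})

test_that("a trace without decay drives the fitted fatigue rate to zero", {
  t <- seq(0, 30, by = 0.05)
  flat <- data.frame(t_s = t, force_norm = pmin(1, t / 1))  # ramp then hold
  fit <- fit_fatigue_parameters(flat)
  expect_lt(fit$params$F, 1e-3)
})

test_that("group-B fitting holds R_B fixed and recovers F_B and r_B", {
  subj <- synthetic_subject(seed = 2)
  pair <- generate_mvc_pair(subj, decay_s = 60, rest_s = 15, probe_s = 6,
                            fs = 20, two_group = TRUE, pct_decay = 20)
  shareA <- 1 - 20 * 0.9 / 100
  fit <- fit_groupB_parameters(pair$decay, pair$probe, shareA = shareA)
  truth <- subj$groupB_fatigue
  expect_equal(fit$params$R, 0.001)
  expect_lt(abs(fit$params$F - truth$F) / truth$F, 0.10)
  expect_lt(abs(fit$params$r_rest - truth$r_rest) / truth$r_rest, 0.10)

  # no group-B force share: unidentifiable, flagged
  fit0 <- fit_groupB_parameters(pair$decay, pair$probe, shareA = 1)
  expect_true(fit0$unidentifiable)
})

test_that("percentage decay is read from plateau and final trimmed means", {
  t <- seq(0, 10, by = 0.01)
  expect_equal(compute_pct_decay(data.frame(t_s = t, force_N = rep(400, length(t)))), 0)
  lin <- data.frame(t_s = t, force_N = seq(400, 300, length.out = length(t)))
  expect_equal(compute_pct_decay(lin), 25, tolerance = 0.02)
  expect_error(compute_pct_decay(data.frame(t_s = c(0, 1), force_N = c(1, 1))),
               "2 s")
  # noisy trace with known 20% underlying decay
  set.seed(5)
  noisy <- data.frame(
    t_s = t,
    force_N = seq(400, 320, length.out = length(t)) + rnorm(length(t), 0, 8)
  )
  expect_equal(compute_pct_decay(noisy), 20, tolerance = 0.05)   # +/- 1 point
})
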