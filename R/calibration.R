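## Subject-specific calibration: actuator strength estimates across postures,
## moment-arm scale k1, maximum-isometric-force scale k2, fatigue-parameter
## fitting from MVC traces, and %decay extraction.

#' Estimate condensed actuator maximum isometric force per posture
#'
#' Treats the flexor group as a single actuator. If the moment arms are
#' correct, the maximum isometric force extracted from a maximal effort
#' should be the same at every posture:
#' `F0 = Q*_max / (J_flex * (f_l * f_v + f_PE))`, where `Q*_max` is the
#' measured maximal flexion moment corrected for the extensor passive
#' moment, and `J_flex`, `f_l`, `f_v`, `f_PE` are actuator means at the
#' posture (pennation taken as zero). The `"static"` variant omits the
#' physiological factor: `F0 = Q*_max / J_flex`.
#'
#' @param Q_max_star measured maximal flexion moments (N*m), one per trial.
#' @param J_flex mean flexor moment arm at each trial's posture (m, > 0).
#' @param phys_factor `f_l * f_v + f_PE` of the actuator at each posture;
#'   ignored when `method = "static"`.
#' @param method `"phys"` (default) or `"static"`.
#' @return numeric vector of actuator `F0` estimates (N), one per trial.
#' @export
estimate_actuator_F0 <- function(Q_max_star, J_flex, phys_factor = NULL,
                                 method = c("phys", "static")) {
  method <- match.arg(method)
  if (any(J_flex <= 0)) {
    stop(sprintf("non-positive flexor moment arm at posture %d",
                 which(J_flex <= 0)[1]))
  }
  if (method == "static") return(Q_max_star / J_flex)
  if (is.null(phys_factor) || any(phys_factor <= 0)) {
    stop(sprintf("non-positive physiological factor at posture %d",
                 if (is.null(phys_factor)) 1L else which(phys_factor <= 0)[1]))
  }
  Q_max_star / (J_flex * phys_factor)
}

#' Mean and sample standard deviation of force estimates
#'
#' @param values numeric vector of at least two force estimates (N).
#' @return list with `mean` and `sd` (sample, n-1 denominator).
#' @export
#' @examples
#' summarize_estimates(c(1912.4, 1857.9, 1426.1, 1415.8,
#'                       1339.0, 1309.5, 1165.6, 1203.9))
summarize_estimates <- function(values) {
  if (length(values) < 2) stop("need at least two estimates")
  list(mean = mean(values), sd = sd(values))
}

## Actuator-level quantities (mean flexor moment arm and mean physiological
## factor) at a set of postures, with alpha = 0 and a = 1 as in the
## calibration derivation. Extensor passive moments give Q*_max from Q_max.
actuator_at_postures <- function(model, phi_deg, phidot_deg_s = 0) {
  interp <- geometry_interpolants(model)
  flex <- which(model$muscles$role == "flexor")
  ext <- which(model$muscles$role == "extensor")
  res <- lapply(phi_deg, function(phi) {
    Jf <- vapply(flex, function(i) interp[[i]]$J(phi), numeric(1))
    phys <- vapply(flex, function(i) {
      mu <- model$muscles[i, ]
      lMT <- interp[[i]]$lMT(phi)
      vMT <- -interp[[i]]$J(phi) * phidot_deg_s * pi / 180
      fs <- fiber_state_rigid_tendon(mu, lMT, vMT, model$curves)
      force_length_active(fs$l_norm, model$curves) *
        force_velocity(fs$v_norm, model$curves) +
        force_length_passive(fs$l_norm, model$curves)
    }, numeric(1))
    Q_ext_passive <- sum(vapply(ext, function(i) {
      mu <- model$muscles[i, ]
      lMT <- interp[[i]]$lMT(phi)
      fs <- fiber_state_rigid_tendon(mu, lMT, 0, model$curves)
      interp[[i]]$J(phi) * force_bounds(mu, fs, model$curves)$f_min
    }, numeric(1)))
    list(J_flex = mean(Jf), phys_factor = mean(phys),
         Q_ext_passive = Q_ext_passive)
  })
  list(
    J_flex = vapply(res, `[[`, numeric(1), "J_flex"),
    phys_factor = vapply(res, `[[`, numeric(1), "phys_factor"),
    Q_ext_passive = vapply(res, `[[`, numeric(1), "Q_ext_passive")
  )
}

#' Calibrate the moment-arm scale factor k1
#'
#' Recalibrates every muscle's moment arm by the anchored affine map
#' `J*(phi) = k1 * (J(phi) - J(0)) + J(0)` (anchored at full extension so
#' the map has a single free parameter), choosing `k1` to minimize the
#' sample standard deviation of the per-trial actuator `F0` estimates
#' recomputed with the recalibrated arms. The identity `k1 = 1` is always in
#' the search interval, so the calibrated SD never exceeds the original.
#'
#' @param postures data frame with columns `phi_deg` (posture) and `Qmax_Nm`
#'   (measured maximal flexion moment, one row per trial; postures may
#'   repeat).
#' @param model a [msk_model()] supplying geometry and passive extensor
#'   moments.
#' @param interval search interval for `k1` (default `[0.05, 20]`).
#' @return list of class `k1_calibration`: `k1`, `model` (with recalibrated
#'   moment arms), `estimates_pre`, `estimates_post`, and pre/post
#'   mean and SD diagnostics.
#' @export
calibrate_moment_arm_scale <- function(postures, model,
                                       interval = c(0.05, 20)) {
  stopifnot(nrow(postures) >= 2, all(c("phi_deg", "Qmax_Nm") %in% names(postures)))
  estimates_for <- function(mdl) {
    act <- actuator_at_postures(mdl, postures$phi_deg)
    Q_star <- postures$Qmax_Nm - act$Q_ext_passive
    estimate_actuator_F0(Q_star, act$J_flex, act$phys_factor)
  }
  rescale <- function(mdl, k1) {
    for (nm in mdl$muscles$name) {
      g <- mdl$geometry[[nm]]
      J0 <- splinefun(g$phi_deg, g$moment_arm_m, method = "natural")(0)
      mdl$geometry[[nm]]$moment_arm_m <- k1 * (g$moment_arm_m - J0) + J0
    }
    mdl
  }
  pre <- estimates_for(model)
  obj <- function(k1) {
    e <- tryCatch(estimates_for(rescale(model, k1)), error = function(e) NULL)
    if (is.null(e) || any(!is.finite(e)) || any(e <= 0)) return(1e12)
    sd(e)
  }
  ## coarse log-spaced scan (identity always included), then local refine in
  ## the bracketing subinterval: robust to penalty plateaus at extreme k1
  grid <- sort(unique(c(1, exp(seq(log(interval[1]), log(interval[2]),
                                   length.out = 61)))))
  gv <- vapply(grid, obj, numeric(1))
  i0 <- which.min(gv)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(obj, interval = c(lo, hi), tol = 1e-8)
  k1 <- if (opt$objective <= min(gv[i0], obj(1))) opt$minimum else 1
  model_cal <- rescale(model, k1)
  post <- estimates_for(model_cal)
  structure(
    list(
      k1 = k1, model = model_cal,
      estimates_pre = pre, estimates_post = post,
      pre = summarize_estimates(pre), post = summarize_estimates(post)
    ),
    class = "k1_calibration"
  )
}

#' Calibrate the maximum isometric force scale k2
#'
#' During an MVC the flexors are assumed fully active and the extensors
#' passive, so the model's maximal flexion moment `Q_max,flex(t)` can be
#' compared with the measured moment: `k2(t) = Q(t) / Q_max,flex(t)`. Every
#' muscle's maximum isometric force (extensors included) is then scaled by
#' `max_t k2(t)` so the model can just reproduce the strongest measured
#' instant.
#'
#' @param Q_trace data frame with columns `t_s` and `Q_Nm`: measured flexion
#'   moment during an MVC.
#' @param model a [msk_model()].
#' @param phi_deg elbow angle during the (isometric) MVC, scalar or vector
#'   matching the trace.
#' @return list of class `k2_calibration`: `k2` (the applied max), `k2_t`
#'   (pointwise trace), and `model` with scaled `F0M`.
#' @export
calibrate_F0_scale <- function(Q_trace, model, phi_deg = 50) {
  phi <- rep_len(phi_deg, nrow(Q_trace))
  Qcap <- vapply(unique(phi), function(p) {
    available_max_moment(model, p, Mf = rep(0, nrow(model$muscles)))
  }, numeric(1))
  names(Qcap) <- as.character(unique(phi))
  cap <- Qcap[as.character(phi)]
  if (any(cap <= 0)) stop("model maximal flexion moment is non-positive at the MVC posture")
  k2_t <- Q_trace$Q_Nm / cap
  k2 <- max(k2_t)
  model$muscles$F0M <- model$muscles$F0M * k2
  structure(list(k2 = k2, k2_t = k2_t, model = model),
            class = "k2_calibration")
}

## Forward model for fatigue-parameter fitting: normalized force during
## effort segments equals the active compartment Ma/100 at TL = 100, with
## TL = 0 (rest recovery) between efforts. `segments` is a data frame with
## columns start_s, end_s (effort windows on the trace clock).
simulate_mvc_capacity <- function(params, times, segments, dt = 0.05,
                                  two_group = NULL) {
  horizon <- max(times)
  tl_fn <- function(t) {
    if (any(t >= segments$start_s & t < segments$end_s)) 100 else 0
  }
  if (is.null(two_group)) {
    traj <- ccr_simulate(tl_fn, params, horizon + dt, dt = dt)
    approx(traj$t_s, traj$Ma / 100, xout = times, rule = 2)$y
  } else {
    ## two fiber groups loaded in parallel: total normalized force is the
    ## F0-weighted sum of group active compartments
    trajA <- ccr_simulate(tl_fn, two_group$paramsA, horizon + dt, dt = dt)
    trajB <- ccr_simulate(tl_fn, params, horizon + dt, dt = dt)
    wA <- two_group$shareA; wB <- 1 - two_group$shareA
    fA <- approx(trajA$t_s, trajA$Ma / 100, xout = times, rule = 2)$y
    fB <- approx(trajB$t_s, trajB$Ma / 100, xout = times, rule = 2)$y
    wA * fA + wB * fB
  }
}

#' Fit fatigue parameters to measured MVC force traces
#'
#' Least-squares fit of the 3CCr model to normalized force measured during a
#' sustained maximal effort (which identifies the fatigue rate `F`) and a
#' post-rest maximal probe (which identifies `R` and `r_rest`). The forward
#' model drives the compartments with a target load of 100% during effort
#' windows and 0 during rest, and predicts normalized force as the active
#' compartment `Ma / 100`.
#'
#' @param decay_trace data frame `t_s`, `force_norm` (force normalized to
#'   the baseline maximum) sampled during the sustained effort.
#' @param recovery_probe like `decay_trace`, sampled during a second maximal
#'   effort after a rest; its `t_s` is on the same clock (i.e., continues
#'   after the rest gap).
#' @param initial starting [fatigue_params()] for the optimizer.
#' @param dt forward-simulation step (s, default 0.05).
#' @param lower,upper box bounds on `(F, R, r_rest)`.
#' @return list of class `fatigue_fit`: fitted `params`, `residual_norm`,
#'   and the `nlminb` convergence object.
#' @export
fit_fatigue_parameters <- function(decay_trace, recovery_probe = NULL,
                                   initial = fatigue_params(0.01, 0.01, 10),
                                   dt = 0.05,
                                   lower = c(1e-5, 1e-5, 1),
                                   upper = c(1, 1, 50)) {
  traces <- list(decay_trace)
  segs <- data.frame(start_s = min(decay_trace$t_s),
                     end_s = max(decay_trace$t_s) + dt)
  if (!is.null(recovery_probe)) {
    traces <- c(traces, list(recovery_probe))
    segs <- rbind(segs, data.frame(start_s = min(recovery_probe$t_s),
                                   end_s = max(recovery_probe$t_s) + dt))
  }
  obs <- do.call(rbind, traces)
  resid_fn <- function(theta) {
    p <- fatigue_params(theta[1], theta[2], theta[3])
    pred <- simulate_mvc_capacity(p, obs$t_s, segs, dt = dt)
    r <- pred - obs$force_norm
    if (any(!is.finite(r))) stop("non-finite residual in fatigue fit")
    sum(r^2)
  }
  fit <- nlminb(c(initial$F, initial$R, initial$r_rest), resid_fn,
                lower = lower, upper = upper,
                control = list(abs.tol = 1e-12, rel.tol = 1e-10,
                               x.tol = 1e-10, iter.max = 500))
  structure(
    list(
      params = fatigue_params(fit$par[1], fit$par[2], fit$par[3]),
      residual_norm = sqrt(fit$objective),
      fit = fit
    ),
    class = "fatigue_fit"
  )
}

#' Fit group-B fatigue parameters with a frozen recovery rate
#'
#' Fits the fast-fatigable fiber group's fatigue rate `F_B` and rest
#' multiplier `r_B` to MVC traces, with the group-B recovery coefficient
#' frozen (default `R_B = 0.001` 1/s, reflecting anaerobic metabolism). The
#' fatigue-resistant group A contributes to the forward model with fixed
#' parameters (`F_A = 0.004`, `R_A = 0.01`, `r_A = 1`) and its share of the
#' maximum isometric force, and is subtracted implicitly by fitting the
#' summed two-group force.
#'
#' @inheritParams fit_fatigue_parameters
#' @param R_B_fixed frozen group-B recovery rate (1/s, default 0.001).
#' @param shareA group-A share of maximum isometric force (0-1), e.g.
#'   `1 - pct_decay * 0.9 / 100`.
#' @param paramsA fixed group-A [fatigue_params()].
#' @return list of class `fatigue_fit` with fitted `params` (F = F_B,
#'   R = R_B_fixed, r_rest = r_B); an `unidentifiable` flag is set when the
#'   group-B force share is (near) zero.
#' @export
fit_groupB_parameters <- function(decay_trace, recovery_probe = NULL,
                                  R_B_fixed = 0.001, shareA = 0.82,
                                  paramsA = fatigue_params(0.004, 0.01, 1),
                                  initial = fatigue_params(0.1, 0.001, 10),
                                  dt = 0.05,
                                  lower = c(1e-5, 1), upper = c(1, 50)) {
  stopifnot(R_B_fixed > 0, shareA >= 0, shareA <= 1)
  if (shareA >= 1 - 1e-9) {
    return(structure(
      list(params = fatigue_params(initial$F, R_B_fixed, initial$r_rest),
           residual_norm = NA_real_, fit = NULL, unidentifiable = TRUE),
      class = "fatigue_fit"
    ))
  }
  traces <- list(decay_trace)
  segs <- data.frame(start_s = min(decay_trace$t_s),
                     end_s = max(decay_trace$t_s) + dt)
  if (!is.null(recovery_probe)) {
    traces <- c(traces, list(recovery_probe))
    segs <- rbind(segs, data.frame(start_s = min(recovery_probe$t_s),
                                   end_s = max(recovery_probe$t_s) + dt))
  }
  obs <- do.call(rbind, traces)
  two_group <- list(paramsA = paramsA, shareA = shareA)
  resid_fn <- function(theta) {
    p <- fatigue_params(theta[1], R_B_fixed, theta[2])
    pred <- simulate_mvc_capacity(p, obs$t_s, segs, dt = dt,
                                  two_group = two_group)
    r <- pred - obs$force_norm
    if (any(!is.finite(r))) stop("non-finite residual in fatigue fit")
    sum(r^2)
  }
  fit <- nlminb(c(initial$F, initial$r_rest), resid_fn,
                lower = lower, upper = upper,
                control = list(abs.tol = 1e-12, rel.tol = 1e-10,
                               x.tol = 1e-10, iter.max = 500))
  structure(
    list(
      params = fatigue_params(fit$par[1], R_B_fixed, fit$par[2]),
      residual_norm = sqrt(fit$objective),
      fit = fit, unidentifiable = FALSE
    ),
    class = "fatigue_fit"
  )
}

#' Percentage of force decay in a sustained maximal effort
#'
#' `%decay = 100 * (peak plateau force - final force) / peak plateau force`.
#' The peak plateau force and the final force are each estimated from a
#' 0.5-s local linear fit evaluated at the window edge (the plateau-start
#' window is the one with the largest mean). The local fit keeps the
#' estimate robust to gauge noise without the downward averaging bias a
#' plain window mean has on steadily decaying traces.
#'
#' @param trace data frame with columns `t_s` and `force_N` (or
#'   `force_norm`) spanning a sustained maximal effort of at least 2 s.
#' @param window fit window (s, default 0.5).
#' @return percentage decay (0-100).
#' @export
compute_pct_decay <- function(trace, window = 0.5) {
  tcol <- trace$t_s
  f <- if ("force_N" %in% names(trace)) trace$force_N else trace$force_norm
  if (diff(range(tcol)) < 2) stop("trace must span at least 2 s of sustained effort")
  dtm <- stats::median(diff(tcol))
  k <- max(2L, round(window / dtm))
  roll <- stats::filter(f, rep(1 / k, k), sides = 1)
  i_peak <- which.max(roll)                     # window f[(i-k+1)..i]
  edge_fit <- function(idx, at) {
    ft <- stats::lm.fit(cbind(1, tcol[idx] - at), f[idx])
    unname(ft$coefficients[1])
  }
  peak <- edge_fit(seq(i_peak - k + 1, i_peak), tcol[i_peak - k + 1])
  final <- edge_fit(seq(length(f) - k + 1, length(f)), tcol[length(f)])
  100 * (peak - final) / peak
}
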