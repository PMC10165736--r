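## Session-level coupling of load sharing and fatigue: at each time step the
## redundancy problem is solved under fatigue-modified force ceilings, the
## resulting activations define per-muscle target loads, and those target
## loads advance the compartment states to the next instant (an explicit
## one-step lag).

## Muscle-wise fatigue state container: vectors over the model's muscles.
session_states <- function(model) {
  m <- nrow(model$muscles)
  ccr_state(Ma = rep(0, m), Mr = rep(100, m), Mf = rep(0, m))
}

muscle_fatigue_params <- function(model) {
  fatigue_params(model$muscles$F, model$muscles$R, model$muscles$r_rest)
}

## Precomputed, vectorized view of a model for tight simulation loops.
session_context <- function(model) {
  mus <- model$muscles
  list(
    model = model,
    interp = geometry_interpolants(model),
    m = nrow(mus),
    name = mus$name,
    flex = mus$role == "flexor",
    F0M = mus$F0M, l0M = mus$l0M, lST = mus$lST,
    h = mus$l0M * sin(mus$alpha0),
    weights = mus$F,
    params = muscle_fatigue_params(model),
    curves = model$curves
  )
}

## Fiber mechanics and fatigue-modified bounds for all muscles at one
## posture, vectorized across muscles.
instant_mechanics <- function(ctx, phi, phidot_deg_s, Mf) {
  J <- unname(vapply(ctx$interp, function(g) g$J(phi), numeric(1)))
  lMT <- unname(vapply(ctx$interp, function(g) g$lMT(phi), numeric(1)))
  proj <- lMT - ctx$lST
  if (any(proj <= 0)) {
    stop(sprintf(
      "infeasible geometry for muscle '%s' at %.1f deg: musculotendon length below tendon slack length",
      ctx$name[which(proj <= 0)[1]], phi
    ))
  }
  lM <- sqrt(proj^2 + ctx$h^2)
  alpha <- atan2(ctx$h, proj)
  ca <- cos(alpha)
  vMT <- -J * phidot_deg_s * pi / 180
  l_norm <- lM / ctx$l0M
  v_norm <- vMT * ca / (ctx$curves$v_max_factor * ctx$l0M)
  fl <- force_length_active(l_norm, ctx$curves)
  fv <- force_velocity(v_norm, ctx$curves)
  fpe <- force_length_passive(l_norm, ctx$curves)
  lower <- fpe * ctx$F0M * ca
  upper <- (fl * fv * (100 - Mf) / 100 + fpe) * ctx$F0M * ca
  list(J = J, lower = lower, upper = upper,
       fl = fl, fv = fv, fpe = fpe, ca = ca,
       l_norm = l_norm, v_norm = v_norm)
}

## Vectorized activation back-computation against fatigue-adjusted ceilings;
## forces are assumed within bounds (they come from the solver).
mech_activations <- function(ctx, mech, forces, Mf) {
  fce <- mech$fl * mech$fv * ctx$F0M * (100 - Mf) / 100
  a <- ifelse(fce > .Machine$double.eps,
              (forces / mech$ca - mech$fpe * ctx$F0M) / fce, 0)
  pmin(pmax(a, 0), 1)
}

#' One coupled load-sharing / fatigue time step
#'
#' Executes one instant of the coupled loop: (1) fatigue-modified force
#' ceilings are computed from the current compartment states; (2) the
#' load-sharing problem is solved for the net torque `Q`; (3) activations
#' are back-computed against the fatigue-adjusted contractile capacity; (4)
#' per-muscle target loads `TL_i = 100 * a_i` advance the compartment states
#' by `dt`. Infeasible torque demands are clamped and reported through the
#' solution's `torque_residual`, and the simulation continues.
#'
#' @param model a [msk_model()].
#' @param states current per-muscle [ccr_state()] (vector components).
#' @param sample list or one-row data frame with `phi` (deg), `phidot`
#'   (deg/s) and `Q` (N*m).
#' @param dt time step (s).
#' @param criterion `"sumsq"` (classical) or `"fatigue-weighted"`
#'   (size-principle) recruitment criterion.
#' @param ctx optional precomputed session context (internal; built from
#'   the model when omitted).
#' @return list with `solution` (a `load_sharing_solution` with
#'   activations), `states` (advanced compartment states), `tl` (the applied
#'   target loads) and `available_moment` (N*m at the current instant).
#' @export
run_timestep <- function(model, states, sample, dt = 0.01,
                         criterion = c("sumsq", "fatigue-weighted"),
                         ctx = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(ctx)) ctx <- session_context(model)
  mech <- instant_mechanics(ctx, sample$phi,
                            if (is.null(sample$phidot)) 0 else sample$phidot,
                            states$Mf)
  sol <- withCallingHandlers(
    if (criterion == "sumsq") {
      solve_min_sum_squares(mech$J, sample$Q, mech$lower, mech$upper)
    } else {
      solve_fatigue_weighted(mech$J, sample$Q, mech$lower, mech$upper,
                             weights = ctx$weights)
    },
    warning = function(w) invokeRestart("muffleWarning")
  )
  sol$activations <- mech_activations(ctx, mech, sol$forces, states$Mf)
  tl <- 100 * sol$activations
  avail <- sum(mech$J[ctx$flex] * mech$upper[ctx$flex]) +
    sum(mech$J[!ctx$flex] * mech$lower[!ctx$flex])
  states <- ccr_step(states, tl, ctx$params, dt)
  list(solution = sol, states = states, tl = tl, available_moment = avail)
}

#' Available maximal flexion moment under fatigue
#'
#' The net flexion moment the model can produce at a posture when all
#' flexors exert their fatigue-modified maximum force and the extensors
#' their passive minimum:
#' `sum_flexors J_i * F_ceiling_i + sum_extensors J_i * f_min_i`.
#'
#' @param model a [msk_model()].
#' @param phi elbow angle (deg).
#' @param Mf per-muscle fatigued percentage (default all 0).
#' @param phidot angular velocity (deg/s, default 0).
#' @param ctx optional precomputed session context (internal).
#' @return available maximal flexion moment (N*m).
#' @export
available_max_moment <- function(model, phi, Mf = NULL, phidot = 0,
                                 ctx = NULL) {
  if (is.null(ctx)) ctx <- session_context(model)
  if (is.null(Mf)) Mf <- rep(0, ctx$m)
  mech <- instant_mechanics(ctx, phi, phidot, Mf)
  sum(mech$J[ctx$flex] * mech$upper[ctx$flex]) +
    sum(mech$J[!ctx$flex] * mech$lower[!ctx$flex])
}

#' Predict time to failure of a static hold
#'
#' Simulates the coupled loop holding a constant torque at a fixed posture
#' until the available maximal flexion moment drops below the demand. The
#' failure instant is linearly interpolated between the bracketing steps.
#'
#' @param model a [msk_model()].
#' @param Q_const held flexion torque (N*m), below the rested capacity.
#' @param phi elbow angle of the hold (deg).
#' @param dt time step (s, default 0.01).
#' @param horizon maximum simulated time (s, default 600).
#' @param criterion recruitment criterion, see [run_timestep()].
#' @return list with `failure_time_s` (`NA` if censored), `censored`, and a
#'   `trace` data frame (`t_s`, `available_Nm`, `torque_residual_Nm`).
#' @export
predict_failure_time <- function(model, Q_const, phi, dt = 0.01,
                                 horizon = 600,
                                 criterion = c("sumsq", "fatigue-weighted")) {
  criterion <- match.arg(criterion)
  ctx <- session_context(model)
  states <- session_states(model)
  n <- ceiling(horizon / dt)
  sample <- list(phi = phi, phidot = 0, Q = Q_const)
  t_out <- numeric(n + 1); avail <- numeric(n + 1); resid <- numeric(n + 1)
  prev_avail <- available_max_moment(model, phi, states$Mf, ctx = ctx)
  t_out[1] <- 0; avail[1] <- prev_avail; resid[1] <- 0
  if (prev_avail < Q_const) {
    return(list(failure_time_s = 0, censored = FALSE,
                trace = data.frame(t_s = 0, available_Nm = prev_avail,
                                   torque_residual_Nm = max(0, Q_const - prev_avail))))
  }
  for (k in seq_len(n)) {
    step <- run_timestep(model, states, sample, dt, criterion, ctx)
    states <- step$states
    a_now <- available_max_moment(model, phi, states$Mf, ctx = ctx)
    t_out[k + 1] <- k * dt
    avail[k + 1] <- a_now
    resid[k + 1] <- step$solution$torque_residual
    if (a_now < Q_const) {
      frac <- (prev_avail - Q_const) / (prev_avail - a_now)
      tf <- (k - 1) * dt + frac * dt
      idx <- seq_len(k + 1)
      return(list(failure_time_s = tf, censored = FALSE,
                  trace = data.frame(t_s = t_out[idx], available_Nm = avail[idx],
                                     torque_residual_Nm = resid[idx])))
    }
    prev_avail <- a_now
  }
  list(failure_time_s = NA_real_, censored = TRUE,
       trace = data.frame(t_s = t_out, available_Nm = avail,
                          torque_residual_Nm = resid))
}

#' Build a task protocol
#'
#' A protocol is an ordered list of segments executed by
#' [simulate_protocol()]. Segment kinds:
#' * `mvc`: sustained maximal effort at a posture (`duration_s`,
#'   `phi_deg`); agonist target loads are forced to 100%.
#' * `static_hold`: constant torque hold (`duration_s`, `phi_deg`, and
#'   either `Q_Nm` or `mass_kg` for a held dumbbell).
#' * `curl_set`: `reps` hammer curls at `cadence_s` seconds per repetition
#'   with a dumbbell of `mass_kg`, elbow sweeping `phi_range_deg`.
#' * `rest`: `duration_s` of rest (target load 0, boosted recovery).
#'
#' Segments may carry a `cycle` integer tag used for cycle-to-cycle
#' equilibrium detection.
#'
#' @param segments list of segment lists, each with a `kind` field.
#' @param subject optional subject parameters for torque generation: list
#'   with `forearm_mass_kg`, `forearm_com_m`, `forearm_inertia_kgm2`,
#'   `forearm_length_m` (see [synthetic_subject()]).
#' @return object of class `protocol`.
#' @export
protocol <- function(segments, subject = NULL) {
  kinds <- vapply(segments, `[[`, character(1), "kind")
  stopifnot(all(kinds %in% c("mvc", "static_hold", "curl_set", "rest")))
  for (s in segments) {
    if (!is.null(s$duration_s) && s$duration_s <= 0) stop("segment durations must be positive")
    if (!is.null(s$reps) && s$reps < 1) stop("curl sets need at least one repetition")
  }
  structure(list(segments = segments, subject = subject), class = "protocol")
}

## Expand one protocol segment into a joint sample table (t relative to the
## segment start). MVC segments carry Q = NA: they bypass load sharing.
segment_samples <- function(seg, subject, dt) {
  if (seg$kind == "rest") {
    n <- ceiling(seg$duration_s / dt)
    return(data.frame(t = seq_len(n) * dt, phi = seg$phi_deg %||% 50,
                      phidot = 0, Q = 0, mvc = FALSE, rest = TRUE))
  }
  if (seg$kind == "mvc") {
    n <- ceiling(seg$duration_s / dt)
    return(data.frame(t = seq_len(n) * dt, phi = seg$phi_deg %||% 50,
                      phidot = 0, Q = NA_real_, mvc = TRUE, rest = FALSE))
  }
  if (seg$kind == "static_hold") {
    n <- ceiling(seg$duration_s / dt)
    Q <- seg$Q_Nm
    if (is.null(Q)) {
      Q <- gravitational_torque(seg$phi_deg, seg$mass_kg, subject)
    }
    return(data.frame(t = seq_len(n) * dt, phi = seg$phi_deg,
                      phidot = 0, Q = Q, mvc = FALSE, rest = FALSE))
  }
  ## curl_set
  motion <- generate_curl_motion(
    reps = seg$reps, period_s = seg$cadence_s,
    phi_range_deg = seg$phi_range_deg %||% c(30, 130),
    subject = subject, mass_kg = seg$mass_kg, dt = dt
  )
  data.frame(t = motion$t_s, phi = motion$phi_deg, phidot = motion$phidot_deg_s,
             Q = motion$Q_Nm, mvc = FALSE, rest = FALSE)[-1, ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full task protocol
#'
#' Executes protocol segments in order through the coupled load-sharing /
#' fatigue loop. Rest segments apply a zero target load (engaging the rest
#' recovery multiplier); MVC segments force the agonist (flexor) target
#' loads to 100% and the extensors to 0 while recording the available
#' maximal flexion moment; curl sets generate hammer-curl kinematics and
#' torques from the subject parameters. If segments carry `cycle` tags, the
#' fatigued-compartment change between consecutive cycle ends is monitored
#' and an equilibrium flag raised when every muscle changes by less than
#' `eq_tol` percent motor units per cycle.
#'
#' @param model a [msk_model()].
#' @param prot a [protocol()].
#' @param dt time step (s, default 0.01).
#' @param criterion recruitment criterion, see [run_timestep()].
#' @param eq_tol cycle-to-cycle equilibrium threshold (% motor units,
#'   default 0.01).
#' @return object of class `session_result`: list with `timeseries` (data
#'   frame: `t_s`, `segment`, `kind`, `phi_deg`, `Q_Nm`, `available_Nm`,
#'   `torque_residual_Nm`), matrices `forces_N`, `activations`, `Ma`, `Mr`,
#'   `Mf` (time x muscle), `muscles`, and `events` (failure instants during
#'   holds/curls, equilibrium detection).
#' @export
simulate_protocol <- function(model, prot, dt = 0.01,
                              criterion = c("sumsq", "fatigue-weighted"),
                              eq_tol = 0.01) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(prot, "protocol"))
  ctx <- session_context(model)
  params <- ctx$params
  m <- ctx$m
  flex <- ctx$flex
  states <- session_states(model)

  seg_tabs <- lapply(prot$segments, segment_samples, subject = prot$subject,
                     dt = dt)
  n_tot <- sum(vapply(seg_tabs, nrow, integer(1)))
  ts <- data.frame(t_s = numeric(n_tot), segment = integer(n_tot),
                   kind = character(n_tot), phi_deg = numeric(n_tot),
                   Q_Nm = numeric(n_tot), available_Nm = numeric(n_tot),
                   torque_residual_Nm = numeric(n_tot))
  forces <- matrix(NA_real_, n_tot, m); acts <- matrix(NA_real_, n_tot, m)
  Ma <- matrix(NA_real_, n_tot, m); Mr <- matrix(NA_real_, n_tot, m)
  Mf <- matrix(NA_real_, n_tot, m)

  t0 <- 0; row <- 0
  failures <- data.frame(t_s = numeric(0), segment = integer(0))
  cycle_ends <- list()
  for (si in seq_along(prot$segments)) {
    seg <- prot$segments[[si]]
    tab <- seg_tabs[[si]]
    for (k in seq_len(nrow(tab))) {
      row <- row + 1
      phi <- tab$phi[k]; phidot <- tab$phidot[k]
      if (tab$rest[k]) {
        tl <- rep(0, m)
        states <- ccr_step(states, tl, params, dt)
        avail <- NA_real_; f <- rep(NA_real_, m); a <- rep(0, m); resid <- 0
        Qk <- 0
      } else if (tab$mvc[k]) {
        mech <- instant_mechanics(ctx, phi, phidot, states$Mf)
        avail <- sum(mech$J[flex] * mech$upper[flex]) +
          sum(mech$J[!flex] * mech$lower[!flex])
        f <- ifelse(flex, mech$upper, mech$lower)
        a <- ifelse(flex, 1, 0)
        tl <- ifelse(flex, 100, 0)
        states <- ccr_step(states, tl, params, dt)
        resid <- 0; Qk <- avail
      } else {
        sample <- list(phi = phi, phidot = phidot, Q = tab$Q[k])
        step <- run_timestep(model, states, sample, dt, criterion, ctx)
        states <- step$states
        avail <- step$available_moment
        f <- step$solution$forces
        a <- step$solution$activations
        resid <- step$solution$torque_residual
        Qk <- tab$Q[k]
        if (resid > 1e-9 && avail < tab$Q[k]) {
          failures <- rbind(failures,
                            data.frame(t_s = t0 + tab$t[k], segment = si))
        }
      }
      ts$t_s[row] <- t0 + tab$t[k]; ts$segment[row] <- si
      ts$kind[row] <- seg$kind; ts$phi_deg[row] <- phi
      ts$Q_Nm[row] <- Qk; ts$available_Nm[row] <- avail
      ts$torque_residual_Nm[row] <- resid
      forces[row, ] <- f; acts[row, ] <- a
      Ma[row, ] <- states$Ma; Mr[row, ] <- states$Mr; Mf[row, ] <- states$Mf
    }
    t0 <- t0 + tab$t[nrow(tab)]
    if (!is.null(seg$cycle)) {
      cycle_ends[[as.character(seg$cycle)]] <- states$Mf
    }
  }

  equilibrium <- NA
  delta_Mf <- NULL
  if (length(cycle_ends) >= 2) {
    ends <- do.call(rbind, cycle_ends)
    delta_Mf <- apply(abs(diff(ends)), 1, max)
    equilibrium <- tail(delta_Mf, 1) < eq_tol
  }

  structure(
    list(
      timeseries = ts, forces_N = forces, activations = acts,
      Ma = Ma, Mr = Mr, Mf = Mf, muscles = model$muscles$name,
      events = list(failures = failures, equilibrium = equilibrium,
                    cycle_delta_Mf = delta_Mf)
    ),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result: %d steps, %d muscles, %.1f s>\n",
              nrow(x$timeseries), length(x$muscles), max(x$timeseries$t_s)))
  if (nrow(x$events$failures)) {
    cat(sprintf("  first torque deficit at t = %.2f s\n",
                min(x$events$failures$t_s)))
  }
  if (!is.na(x$events$equilibrium)) {
    cat(sprintf("  cycle equilibrium: %s\n", x$events$equilibrium))
  }
  invisible(x)
}

#' Compare simulated and measured MVC moment traces
#'
#' Root-mean-square error per analysis window and the first-peak error
#' (simulated minus measured peak within the first window). Traces are
#' interpolated onto the measured clock inside each window.
#'
#' @param simulated,measured data frames with columns `t_s` and `Q_Nm` on a
#'   shared clock.
#' @param windows list of `c(start_s, end_s)` windows; default one window
#'   spanning the measured trace.
#' @return list with `rmse_Nm` (one value per window) and
#'   `first_peak_error_Nm`.
#' @export
compare_mvc <- function(simulated, measured, windows = NULL) {
  if (is.null(windows)) windows <- list(range(measured$t_s))
  rmse <- vapply(windows, function(w) {
    idx <- measured$t_s >= w[1] & measured$t_s <= w[2]
    if (!any(idx)) stop(sprintf("empty comparison window [%g, %g]", w[1], w[2]))
    sim <- approx(simulated$t_s, simulated$Q_Nm, xout = measured$t_s[idx],
                  rule = 2)$y
    sqrt(mean((sim - measured$Q_Nm[idx])^2))
  }, numeric(1))
  w1 <- windows[[1]]
  idx1 <- measured$t_s >= w1[1] & measured$t_s <= w1[2]
  sim1 <- approx(simulated$t_s, simulated$Q_Nm, xout = measured$t_s[idx1],
                 rule = 2)$y
  list(rmse_Nm = rmse,
       first_peak_error_Nm = max(sim1) - max(measured$Q_Nm[idx1]))
}
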