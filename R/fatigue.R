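## Revised three-compartment controller (3CCr) muscle fatigue model.
##
## Motor units flow between active (Ma), resting (Mr) and fatigued (Mf)
## compartments, each expressed as a percentage of the motor-unit pool so
## Ma + Mr + Mf = 100 at all times. A feedback controller moves units between
## Mr and Ma to track a target load TL (% of maximum); active units fatigue
## at rate F and fatigued units recover at rate R, boosted by the rest
## multiplier r_rest whenever TL = 0.
##
## Note on the compartment equations: the conservation-consistent form is
## used throughout (dMa/dt = C - F*Ma, dMf/dt = F*Ma - R*r*Mf,
## dMr/dt = -C + R*r*Mf). Printed variants of this model sometimes carry the
## recovery rate R in the active-compartment drain; that form does not
## conserve the motor-unit pool and is treated here as a typo.

#' Fatigue parameter set
#'
#' @param F fatigue rate (1/s, > 0): fraction of active motor units moving to
#'   the fatigued compartment per second.
#' @param R recovery rate (1/s, > 0): fraction of fatigued motor units
#'   recovering per second during activity.
#' @param r_rest rest recovery multiplier (>= 1) applied to `R` whenever the
#'   target load is zero.
#' @return list of class `fatigue_params`.
#' @export
#' @examples
#' fatigue_params(F = 0.004, R = 0.01)  # slow-fiber (group A) values
fatigue_params <- function(F, R, r_rest = 1) {
  stopifnot(F > 0, R > 0, r_rest >= 1)
  structure(list(F = F, R = R, r_rest = r_rest), class = "fatigue_params")
}

#' Compartment state
#'
#' @param Ma active motor units (% of pool).
#' @param Mr resting motor units (% of pool).
#' @param Mf fatigued motor units (% of pool).
#' @return list of class `ccr_state`. Components must be non-negative and sum
#'   to 100 (checked to 1e-6).
#' @export
ccr_state <- function(Ma = 0, Mr = 100, Mf = 0) {
  stopifnot(all(Ma >= 0), all(Mr >= 0), all(Mf >= 0))
  if (any(abs(Ma + Mr + Mf - 100) > 1e-6)) {
    stop("compartments must sum to 100 % of motor units")
  }
  structure(list(Ma = Ma, Mr = Mr, Mf = Mf), class = "ccr_state")
}

#' Feedback controller drive
#'
#' Piecewise controller moving motor units between the resting and active
#' compartments to track the target load: `C = TL - Ma` while enough resting
#' units remain (`Mr > TL - Ma`), `C = Mr` when the resting pool limits
#' recruitment, and `C = TL - Ma` (negative, deactivating) when more units
#' are active than needed. At the boundary `Ma = TL` the drive is zero.
#' Vectorized over muscles.
#'
#' @param state a [ccr_state()] (components may be vectors).
#' @param tl target load, % of maximum (0-100), scalar or vector.
#' @return controller drive C (% motor units / s).
#' @export
#' @examples
#' ccr_controller(ccr_state(0, 100, 0), 50)  # 50
#' ccr_controller(ccr_state(0, 30, 70), 50)  # 30, capacity-limited
#' ccr_controller(ccr_state(80, 20, 0), 50)  # -30, deactivating
ccr_controller <- function(state, tl) {
  stopifnot(all(tl >= 0), all(tl <= 100))
  deficit <- tl - state$Ma
  ifelse(deficit > 0, pmin(deficit, state$Mr), deficit)
}

.ccr_rates <- function(Ma, Mr, Mf, tl, F, R, r_rest) {
  deficit <- tl - Ma
  C <- ifelse(deficit > 0, pmin(deficit, Mr), deficit)
  r <- ifelse(tl > 0, 1, r_rest)
  rec <- R * r * Mf
  fat <- F * Ma
  list(dMr = -C + rec, dMa = C - fat, dMf = fat - rec)
}

#' Compartment time derivatives
#'
#' `dMr/dt = -C + R*r*Mf`, `dMa/dt = C - F*Ma`, `dMf/dt = F*Ma - R*r*Mf`,
#' with `r = 1` while the target load is positive and `r = r_rest` at rest.
#' The three derivatives sum to zero, preserving the motor-unit pool.
#'
#' @inheritParams ccr_controller
#' @param params a [fatigue_params()] (components may be vectors, recycled
#'   against the state).
#' @return list with `dMa`, `dMr`, `dMf` (% motor units / s).
#' @export
ccr_derivatives <- function(state, tl, params) {
  d <- .ccr_rates(state$Ma, state$Mr, state$Mf, tl,
                  params$F, params$R, params$r_rest)
  list(dMa = d$dMa, dMr = d$dMr, dMf = d$dMf)
}

#' Advance the compartment state by one time step
#'
#' Classical fixed-step fourth-order Runge-Kutta step of the compartment
#' equations, holding the target load constant over the step. The result is
#' clipped at zero and renormalized to sum exactly 100 as a numerical guard.
#'
#' @inheritParams ccr_derivatives
#' @param dt step size (s, > 0).
#' @return updated [ccr_state()].
#' @export
ccr_step <- function(state, tl, params, dt) {
  stopifnot(dt > 0)
  F <- params$F; R <- params$R; rr <- params$r_rest
  y <- rbind(state$Ma, state$Mr, state$Mf)
  f <- function(y) {
    d <- .ccr_rates(y[1, ], y[2, ], y[3, ], tl, F, R, rr)
    rbind(d$dMa, d$dMr, d$dMf)
  }
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  y <- pmax(y, 0)
  tot <- y[1, ] + y[2, ] + y[3, ]
  y <- sweep(y, 2, 100 / tot, "*")
  ccr_state(Ma = y[1, ], Mr = y[2, ], Mf = y[3, ])
}

## Lean scalar-state RK4 loop (single muscle): avoids the per-step container
## overhead of ccr_step for long simulations. tl is a per-step vector
## (length n, constant over each step).
.ccr_rk4 <- function(F, R, rr, tl, dt, y0 = c(0, 100, 0)) {
  n <- length(tl)
  out <- matrix(NA_real_, n + 1, 3)
  out[1, ] <- y0
  Ma <- y0[1]; Mr <- y0[2]; Mf <- y0[3]
  h2 <- dt / 2; h6 <- dt / 6
  for (k in seq_len(n)) {
    tlk <- tl[k]
    r <- if (tlk > 0) 1 else rr
    rhs <- function(a, m, f) {
      d <- tlk - a
      C <- if (d > 0) min(d, m) else d
      rec <- R * r * f
      fat <- F * a
      c(C - fat, -C + rec, fat - rec)
    }
    k1 <- rhs(Ma, Mr, Mf)
    k2 <- rhs(Ma + h2 * k1[1], Mr + h2 * k1[2], Mf + h2 * k1[3])
    k3 <- rhs(Ma + h2 * k2[1], Mr + h2 * k2[2], Mf + h2 * k2[3])
    k4 <- rhs(Ma + dt * k3[1], Mr + dt * k3[2], Mf + dt * k3[3])
    Ma <- Ma + h6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    Mr <- Mr + h6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    Mf <- Mf + h6 * (k1[3] + 2 * k2[3] + 2 * k3[3] + k4[3])
    if (Ma < 0) Ma <- 0
    if (Mr < 0) Mr <- 0
    if (Mf < 0) Mf <- 0
    s <- 100 / (Ma + Mr + Mf)
    Ma <- Ma * s; Mr <- Mr * s; Mf <- Mf * s
    out[k + 1, 1] <- Ma; out[k + 1, 2] <- Mr; out[k + 1, 3] <- Mf
  }
  out
}

#' Simulate the fatigue model along a target-load profile
#'
#' Integrates the 3CCr model from the fully rested state (or a supplied
#' initial state) under a time-varying target load.
#'
#' @param tl_fn function of time (s) returning the target load (% of
#'   maximum), or a single number for a constant load.
#' @param params a [fatigue_params()].
#' @param duration total simulated time (s, > 0).
#' @param dt integration step (s, default 0.01).
#' @param init optional initial [ccr_state()]; defaults to `Mr = 100`.
#' @return data frame with columns `t_s`, `Ma`, `Mr`, `Mf`, `TL`.
#' @export
#' @examples
#' traj <- ccr_simulate(100, fatigue_params(0.004, 0.01), duration = 120)
#' tail(traj, 1)$Mf  # ~23 % fatigued after 120 s of maximal effort
ccr_simulate <- function(tl_fn, params, duration, dt = 0.01, init = NULL) {
  stopifnot(duration > 0)
  if (is.numeric(tl_fn)) {
    tl_const <- tl_fn
    tl_fn <- function(t) tl_const
  }
  n <- ceiling(duration / dt)
  times <- seq(0, by = dt, length.out = n + 1)
  state <- if (is.null(init)) ccr_state() else init
  tl <- vapply(times[seq_len(n)], tl_fn, numeric(1))
  stopifnot(all(tl >= 0), all(tl <= 100))
  y <- .ccr_rk4(params$F, params$R, params$r_rest, tl, dt,
                y0 = c(state$Ma, state$Mr, state$Mf))
  data.frame(t_s = times, Ma = y[, 1], Mr = y[, 2], Mf = y[, 3],
             TL = c(tl, tl_fn(times[n + 1])))
}

#' Residual force capacity
#'
#' The fraction of baseline maximum force still available, `100 - Mf`
#' (equivalently `Ma + Mr`): fatigue removes contractile capacity
#' proportionally to the fatigued motor-unit share.
#'
#' @param state a [ccr_state()].
#' @return residual capacity, % of baseline maximum.
#' @export
residual_capacity <- function(state) 100 - state$Mf

#' Endurance asymptote of a sustained maximal effort
#'
#' Under a sustained maximal target load the residual capacity converges to
#' `100 / (F/R + 1)` percent of baseline, the balance point between fatigue
#' outflow and recovery inflow.
#'
#' @param params a [fatigue_params()].
#' @return asymptotic residual capacity (% of baseline maximum).
#' @export
#' @examples
#' endurance_asymptote(fatigue_params(0.004, 0.01))  # 71.43 %
endurance_asymptote <- function(params) {
  stopifnot(params$F > 0, params$R > 0)
  100 / (params$F / params$R + 1)
}

#' Fatigue-modified maximum muscle force
#'
#' Maximum musculotendon force when only the non-fatigued motor units can be
#' recruited: `F_max = (f_l * f_v * (100 - Mf)/100 + f_PE) * F0M * cos(alpha)`.
#' The passive term is unaffected by fatigue. With `Mf = 0` this equals the
#' rested upper bound of [force_bounds()].
#'
#' @inheritParams force_bounds
#' @param Mf fatigued motor units (% of pool), scalar.
#' @return maximum force (N).
#' @export
fatigued_force_ceiling <- function(muscle, fiber, Mf, curves = NULL) {
  fl <- force_length_active(fiber$l_norm, curves)
  fv <- force_velocity(fiber$v_norm, curves)
  fpe <- force_length_passive(fiber$l_norm, curves)
  (fl * fv * (100 - Mf) / 100 + fpe) * muscle$F0M * cos(fiber$alpha)
}
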