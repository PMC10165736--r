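## Rigid-tendon Hill-type musculotendon mechanics.
##
## All fiber mechanics follow from joint kinematics alone (rigid tendon), and
## excitation equals activation (no activation dynamics): the only muscle
## state carried through time is the fatigue compartment state.

#' Default Hill curve shape constants
#'
#' Shape constants for the dimensionless force-length, force-velocity and
#' passive force-length relationships. These can be overridden per call or
#' stored under the `hill_curves` key of a model YAML file.
#'
#' @return A named list:
#' \describe{
#'   \item{fl_width}{Gaussian width of the active force-length curve
#'     (dimensionless, default 0.45).}
#'   \item{fv_shape}{Hill-hyperbola shape constant for concentric
#'     contraction (default 0.25); smaller values give a more concave curve.}
#'   \item{fv_ecc_max}{eccentric force plateau (default 1.4).}
#'   \item{fv_ecc_scale}{normalized-velocity scale of the eccentric rise
#'     (default 0.2).}
#'   \item{pe_shape}{exponential shape of the passive curve (default 5).}
#'   \item{pe_strain}{passive strain at which the passive force reaches the
#'     maximum isometric force (default 0.6).}
#'   \item{v_max_factor}{maximum shortening velocity in optimal fiber lengths
#'     per second (default 10), used to normalize fiber velocity.}
#' }
#' @export
#' @examples
#' hill_curve_defaults()$fl_width
hill_curve_defaults <- function() {
  list(
    fl_width = 0.45,
    fv_shape = 0.25,
    fv_ecc_max = 1.4,
    fv_ecc_scale = 0.2,
    pe_shape = 5,
    pe_strain = 0.6,
    v_max_factor = 10
  )
}

.curves <- function(curves = NULL) {
  def <- hill_curve_defaults()
  if (is.null(curves)) return(def)
  def[names(curves)] <- curves
  def
}

#' Active force-length relationship
#'
#' Dimensionless Gaussian bell centred at the optimal fiber length:
#' `f_l = exp(-((l_norm - 1) / width)^2)`. Equals 1 at `l_norm = 1` and is
#' symmetric about the optimum.
#'
#' @param l_norm fiber length normalized by the optimal fiber length (> 0).
#' @param curves optional list of curve constants (see
#'   [hill_curve_defaults()]); only `fl_width` is used here.
#' @return dimensionless force scale in `[0, 1]`.
#' @export
#' @examples
#' force_length_active(1)      # 1
#' force_length_active(1.45)   # exp(-1)
force_length_active <- function(l_norm, curves = NULL) {
  stopifnot(all(l_norm > 0))
  cv <- .curves(curves)
  exp(-((l_norm - 1) / cv$fl_width)^2)
}

#' Force-velocity relationship
#'
#' Dimensionless force-velocity scale. Shortening velocities are negative
#' (`v_norm = -1` is the maximum shortening velocity, where force is zero);
#' the isometric value is 1; lengthening force rises smoothly to a bounded
#' eccentric plateau. The concentric branch is the classical Hill hyperbola
#' `f_v = (1 + v_norm) / (1 - v_norm / k)` with shape constant `k`.
#'
#' @param v_norm fiber velocity normalized by the maximum shortening
#'   velocity; lengthening positive.
#' @param curves optional curve constants (`fv_shape`, `fv_ecc_max`,
#'   `fv_ecc_scale`).
#' @return dimensionless force scale in `[0, fv_ecc_max]`.
#' @export
#' @examples
#' force_velocity(0)    # 1
#' force_velocity(-1)   # 0
force_velocity <- function(v_norm, curves = NULL) {
  cv <- .curves(curves)
  out <- numeric(length(v_norm))
  conc <- v_norm < 0
  vc <- pmax(v_norm[conc], -1)
  out[conc] <- (1 + vc) / (1 - vc / cv$fv_shape)
  ve <- v_norm[!conc]
  out[!conc] <- 1 + (cv$fv_ecc_max - 1) * ve / (ve + cv$fv_ecc_scale)
  out
}

#' Passive force-length relationship
#'
#' Dimensionless passive (parallel elastic) force. Zero at and below the
#' optimal fiber length, exponentially increasing above it:
#' `f_PE = (exp(k * (l_norm - 1) / e0) - 1) / (exp(k) - 1)` for
#' `l_norm > 1`, so that `f_PE = 1` at a passive strain of `e0`.
#'
#' @inheritParams force_length_active
#' @return dimensionless passive force (>= 0).
#' @export
#' @examples
#' force_length_passive(0.9)  # 0
#' force_length_passive(1.2)
force_length_passive <- function(l_norm, curves = NULL) {
  stopifnot(all(l_norm > 0))
  cv <- .curves(curves)
  strain <- pmax(l_norm - 1, 0)
  (exp(cv$pe_shape * strain / cv$pe_strain) - 1) / (exp(cv$pe_shape) - 1)
}

#' Fiber state under the rigid-tendon assumption
#'
#' With a rigid tendon the fiber length and velocity follow directly from the
#' musculotendon length and velocity. A constant-thickness pennation model is
#' used: the fiber height `l0M * sin(alpha0)` is preserved, so
#' `lM * cos(alpha) = lMT - lST` and `vM = vMT * cos(alpha)`.
#'
#' @param muscle one-row data frame (or list) with fields `name`, `l0M`,
#'   `lST`, `alpha0` (see [muscle_table()]).
#' @param lMT musculotendon length (m); must exceed the tendon slack length.
#' @param vMT musculotendon velocity (m/s, lengthening positive).
#' @param curves optional curve constants (`v_max_factor`).
#' @return an object of class `fiber_state`: list with `lM`, `vM`, `alpha`,
#'   `l_norm`, `v_norm`.
#' @export
#' @examples
#' m <- list(name = "biceps", l0M = 0.12, lST = 0.2, alpha0 = 0)
#' fiber_state_rigid_tendon(m, lMT = 0.32, vMT = 0)$l_norm  # 1
fiber_state_rigid_tendon <- function(muscle, lMT, vMT = 0, curves = NULL) {
  cv <- .curves(curves)
  proj <- lMT - muscle$lST
  if (any(proj <= 0)) {
    stop(sprintf(
      "infeasible geometry for muscle '%s': musculotendon length %.4f m does not exceed tendon slack length %.4f m",
      muscle$name, lMT[which(proj <= 0)[1]], muscle$lST
    ))
  }
  h <- muscle$l0M * sin(muscle$alpha0)
  lM <- sqrt(proj^2 + h^2)
  alpha <- atan2(h, proj)
  vM <- vMT * cos(alpha)
  structure(
    list(
      lM = lM, vM = vM, alpha = alpha,
      l_norm = lM / muscle$l0M,
      v_norm = vM / (cv$v_max_factor * muscle$l0M)
    ),
    class = "fiber_state"
  )
}

#' Physiological force bounds of a muscle
#'
#' Minimum and maximum musculotendon-space forces at the current fiber state,
#' corresponding to zero and full activation of the contractile element:
#' `f_min = f_PE * F0M * cos(alpha)` and
#' `f_max = (f_l * f_v + f_PE) * F0M * cos(alpha)`.
#'
#' @param muscle one-row muscle record with `F0M`.
#' @param fiber a [fiber_state_rigid_tendon()] result.
#' @param curves optional curve constants.
#' @return list of class `force_bounds` with `f_min`, `f_max` (N).
#' @export
force_bounds <- function(muscle, fiber, curves = NULL) {
  fl <- force_length_active(fiber$l_norm, curves)
  fv <- force_velocity(fiber$v_norm, curves)
  fpe <- force_length_passive(fiber$l_norm, curves)
  ca <- cos(fiber$alpha)
  structure(
    list(
      f_min = fpe * muscle$F0M * ca,
      f_max = (fl * fv + fpe) * muscle$F0M * ca
    ),
    class = "force_bounds"
  )
}

#' Back-compute activation from a musculotendon force
#'
#' Inverts the force equilibrium of the Hill model:
#' `a = (f_MT / cos(alpha) - F_PE) / F_CE_max`, where `F_CE_max` is the
#' maximum contractile force at the current fiber state. When a fatigued
#' compartment fraction `Mf` is supplied, the contractile ceiling is reduced
#' to its non-fatigued share `(100 - Mf)/100`, so `a = 1` corresponds to
#' recruiting all *non-fatigued* motor units.
#'
#' @inheritParams force_bounds
#' @param f_MT musculotendon force (N), expected within the (fatigue-adjusted)
#'   physiological bounds.
#' @param Mf fatigued motor units (percent, default 0).
#' @param tol bound-violation tolerance (N) within which the result is
#'   clamped to `[0, 1]`; larger violations raise an error.
#' @return activation in `[0, 1]`.
#' @export
activation_from_force <- function(muscle, fiber, f_MT, Mf = 0, tol = 1e-6,
                                  curves = NULL) {
  fl <- force_length_active(fiber$l_norm, curves)
  fv <- force_velocity(fiber$v_norm, curves)
  fpe <- force_length_passive(fiber$l_norm, curves)
  ca <- cos(fiber$alpha)
  fce_max <- fl * fv * muscle$F0M * (100 - Mf) / 100
  f_pe_force <- fpe * muscle$F0M
  if (fce_max <= .Machine$double.eps) {
    if (abs(f_MT - f_pe_force * ca) <= tol) return(0)
    stop(sprintf(
      "muscle '%s': no contractile capacity at this state but force %.3f N differs from passive force",
      muscle$name, f_MT
    ))
  }
  a <- (f_MT / ca - f_pe_force) / fce_max
  if (a < -tol / fce_max || a > 1 + tol / fce_max) {
    stop(sprintf(
      "muscle '%s': force %.4f N outside physiological bounds (activation %.4f)",
      muscle$name, f_MT, a
    ))
  }
  min(max(a, 0), 1)
}
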