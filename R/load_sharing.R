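## Muscle redundancy (load-sharing) problem at a single time instant:
##
##   minimize   sum_i (w_i * F_i)^2
##   subject to sum_i J_i * F_i = Q,   lb_i <= F_i <= ub_i
##
## with J_i the signed moment arms and Q the net joint torque. This is a
## separable box-constrained quadratic program with one equality constraint;
## the KKT conditions give F_i(lambda) = clamp(lambda * J_i / (2 w_i^2),
## lb_i, ub_i) with the achieved torque piecewise linear and non-decreasing
## in the multiplier lambda, so the optimum is found exactly by a breakpoint
## scan (deterministic, no iterative solver).

solve_qp_dual <- function(J, Q, lb, ub, w) {
  m <- length(J)
  g <- function(lambda) {
    F <- ifelse(abs(J) > 0, lambda * J / (2 * w^2), 0)
    sum(J * pmin(pmax(F, lb), ub))
  }
  ## breakpoints where a muscle enters/leaves its bounds
  bp <- c()
  for (i in seq_len(m)) {
    if (J[i] != 0) bp <- c(bp, 2 * w[i]^2 * lb[i] / J[i], 2 * w[i]^2 * ub[i] / J[i])
  }
  bp <- sort(unique(bp))
  gv <- vapply(bp, g, numeric(1))
  if (Q <= gv[1]) {
    lambda <- bp[1]
  } else if (Q >= gv[length(gv)]) {
    lambda <- bp[length(bp)]
  } else {
    k <- findInterval(Q, gv)          # gv non-decreasing
    ## solve on segment [bp[k], bp[k+1]] where interior slope is constant
    lam0 <- bp[k]; lam1 <- bp[k + 1]
    mid <- (lam0 + lam1) / 2
    Fm <- ifelse(abs(J) > 0, mid * J / (2 * w^2), 0)
    interior <- Fm > lb & Fm < ub & J != 0
    slope <- sum(J[interior]^2 / (2 * w[interior]^2))
    lambda <- if (slope > 0) lam0 + (Q - gv[k]) / slope else lam0
    lambda <- min(max(lambda, lam0), lam1)
  }
  F <- ifelse(abs(J) > 0, lambda * J / (2 * w^2), 0)
  F <- pmin(pmax(F, lb), ub)
  list(F = F, lambda = lambda)
}

.load_sharing <- function(moment_arms, Q, lower, upper, weights) {
  m <- length(moment_arms)
  stopifnot(
    length(lower) == m, length(upper) == m, length(weights) == m,
    all(lower <= upper + 1e-12), all(weights > 0), is.finite(Q)
  )
  if (all(moment_arms == 0)) stop("all moment arms are zero: torque constraint is void")
  Qmin <- sum(moment_arms * ifelse(moment_arms > 0, lower, upper))
  Qmax <- sum(moment_arms * ifelse(moment_arms > 0, upper, lower))
  if (Q > Qmax + 1e-9) {
    F <- ifelse(moment_arms > 0, upper, lower)
    feasible <- FALSE
  } else if (Q < Qmin - 1e-9) {
    F <- ifelse(moment_arms > 0, lower, upper)
    feasible <- FALSE
  } else {
    F <- solve_qp_dual(moment_arms, Q, lower, upper, weights)$F
    feasible <- TRUE
  }
  achieved <- sum(moment_arms * F)
  residual <- if (feasible) 0 else max(0, Q - achieved)
  if (!feasible) {
    warning(sprintf(
      "torque demand %.3f N*m outside achievable range [%.3f, %.3f]: bound-clamped solution returned (residual %.3f N*m)",
      Q, Qmin, Qmax, residual
    ), call. = FALSE)
  }
  structure(
    list(
      forces = F,
      activations = NULL,
      at_upper_bound = F >= upper - 1e-9,
      at_lower_bound = F <= lower + 1e-9,
      torque_residual = residual,
      achieved_torque = achieved,
      feasible = feasible,
      objective_value = sum((F * weights)^2)
    ),
    class = "load_sharing_solution"
  )
}

#' Minimum sum-of-squared-forces load sharing
#'
#' Solves the muscle redundancy problem at one time instant by minimizing
#' the sum of squared muscle forces subject to the net joint torque equality
#' and per-muscle physiological force bounds. If the demanded torque exceeds
#' what the bounds allow, the bound-clamped maximal-torque solution is
#' returned with the unmet torque reported in `torque_residual` and a
#' warning.
#'
#' @param moment_arms signed moment arms (m), positive for flexors and
#'   negative for extensors.
#' @param Q net joint torque to reproduce (N*m, flexion positive).
#' @param lower,upper per-muscle force bounds (N), typically from
#'   [force_bounds()] or [fatigued_force_ceiling()].
#' @return object of class `load_sharing_solution`: list with `forces`,
#'   `at_upper_bound`, `at_lower_bound`, `torque_residual`,
#'   `achieved_torque`, `feasible` and `objective_value`.
#' @export
#' @examples
#' s <- solve_min_sum_squares(c(0.02, 0.04), 2, lower = c(0, 0),
#'                            upper = c(500, 500))
#' s$forces  # 20, 40 N: proportional to the moment arms
solve_min_sum_squares <- function(moment_arms, Q, lower, upper) {
  .load_sharing(moment_arms, Q, lower, upper,
                weights = rep(1, length(moment_arms)))
}

#' Fatigue-weighted load sharing (size-principle recruitment)
#'
#' Minimizes `sum_i (F_i^MT * w_i)^2` under the same torque and bound
#' constraints as [solve_min_sum_squares()], with `w_i` each muscle's
#' fatigue rate. Fatigue-resistant (small-`w`) fibers are therefore loaded
#' preferentially, reproducing the Henneman size-principle recruitment order
#' when muscles are split into fiber-type groups. Equal weights reduce
#' exactly to the classical criterion.
#'
#' @inheritParams solve_min_sum_squares
#' @param weights strictly positive recruitment weights, one per muscle
#'   (the muscle's fatigue rate `F` in 1/s used as a dimensionless
#'   multiplier).
#' @return a `load_sharing_solution` (see [solve_min_sum_squares()]).
#' @export
solve_fatigue_weighted <- function(moment_arms, Q, lower, upper, weights) {
  if (any(weights <= 0)) stop("recruitment weights must be strictly positive")
  .load_sharing(moment_arms, Q, lower, upper, weights = weights)
}

#' Back-compute activations for a load-sharing solution
#'
#' Applies [activation_from_force()] muscle by muscle, optionally against
#' fatigue-reduced contractile ceilings.
#'
#' @param solution a `load_sharing_solution`.
#' @param model the [msk_model()] the solution refers to (muscle order must
#'   match the solver inputs).
#' @param fibers list of [fiber_state_rigid_tendon()] states, one per muscle.
#' @param Mf per-muscle fatigued percentage (default all 0).
#' @return the solution with its `activations` field filled in.
#' @export
solution_activations <- function(solution, model, fibers, Mf = NULL) {
  m <- nrow(model$muscles)
  if (is.null(Mf)) Mf <- rep(0, m)
  solution$activations <- vapply(seq_len(m), function(i) {
    activation_from_force(model$muscles[i, ], fibers[[i]],
                          solution$forces[i], Mf = Mf[i],
                          curves = model$curves)
  }, numeric(1))
  solution
}
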