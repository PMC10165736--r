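## Musculoskeletal model container: muscle parameter table plus per-muscle
## elbow geometry tables (musculotendon length and moment arm as functions of
## the elbow flexion angle).
##
## Angle convention: degrees, 0 deg = full extension, flexion positive.
## Moment arms are signed: positive for flexors, negative for extensors, and
## consistent with J(phi) = -d lMT / d phi (phi in radians).

#' Build a muscle parameter table
#'
#' @param name muscle names (unique).
#' @param role `"flexor"` or `"extensor"` per muscle.
#' @param F0M maximum isometric force (N, > 0).
#' @param l0M optimal fiber length (m, > 0).
#' @param lST tendon slack length (m, >= 0).
#' @param alpha0 pennation angle at optimal fiber length (rad, in
#'   `[0, pi/2)`).
#' @param fiber_group `"A"` (slow/fatigue-resistant), `"B"`
#'   (fast-glycolytic) or `"undivided"`.
#' @param F,R,r_rest per-muscle fatigue parameters (see [fatigue_params()]).
#' @return data frame with one row per muscle.
#' @export
muscle_table <- function(name, role, F0M, l0M, lST, alpha0,
                         fiber_group = "undivided",
                         F = 0.01, R = 0.005, r_rest = 15) {
  df <- data.frame(
    name = as.character(name), role = as.character(role),
    F0M = F0M, l0M = l0M, lST = lST, alpha0 = alpha0,
    fiber_group = fiber_group, F = F, R = R, r_rest = r_rest,
    stringsAsFactors = FALSE
  )
  stopifnot(
    !anyDuplicated(df$name),
    all(df$role %in% c("flexor", "extensor")),
    all(df$F0M >= 0), all(df$l0M > 0), all(df$lST >= 0),
    all(df$alpha0 >= 0), all(df$alpha0 < pi / 2),
    all(df$fiber_group %in% c("A", "B", "undivided")),
    all(df$F > 0), all(df$R > 0), all(df$r_rest >= 1)
  )
  df
}

#' Construct a musculoskeletal model
#'
#' @param muscles a [muscle_table()].
#' @param geometry named list (one entry per muscle) of geometry tables, each
#'   a list with numeric vectors `phi_deg` (strictly increasing elbow angle),
#'   `lMT_m` (musculotendon length) and `moment_arm_m` (signed moment arm).
#' @param variant model variant tag: `"2M"`, `"7M"` or `"14M"`.
#' @param curves optional Hill curve constants stored with the model (see
#'   [hill_curve_defaults()]).
#' @return object of class `msk_model`.
#' @export
msk_model <- function(muscles, geometry, variant = "7M", curves = NULL) {
  stopifnot(
    variant %in% c("2M", "7M", "14M"),
    any(muscles$role == "flexor"), any(muscles$role == "extensor"),
    setequal(names(geometry), muscles$name)
  )
  for (nm in muscles$name) {
    g <- geometry[[nm]]
    stopifnot(
      is.numeric(g$phi_deg), is.numeric(g$lMT_m), is.numeric(g$moment_arm_m),
      length(g$phi_deg) == length(g$lMT_m),
      length(g$phi_deg) == length(g$moment_arm_m),
      all(diff(g$phi_deg) > 0)
    )
    lST <- muscles$lST[muscles$name == nm]
    if (any(g$lMT_m <= lST)) {
      stop(sprintf("muscle '%s': musculotendon length table crosses the tendon slack length", nm))
    }
    role <- muscles$role[muscles$name == nm]
    sgn <- if (role == "flexor") 1 else -1
    if (any(sgn * g$moment_arm_m <= 0)) {
      stop(sprintf("muscle '%s': moment arm sign inconsistent with role '%s'", nm, role))
    }
  }
  structure(
    list(muscles = muscles, geometry = geometry, variant = variant,
         curves = .curves(curves)),
    class = "msk_model"
  )
}

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("<msk_model %s: %d muscles (%d flexors, %d extensors)>\n",
              x$variant, nrow(x$muscles),
              sum(x$muscles$role == "flexor"),
              sum(x$muscles$role == "extensor")))
  print(x$muscles[, c("name", "role", "F0M", "l0M", "lST", "fiber_group")],
        row.names = FALSE)
  invisible(x)
}

## Cubic interpolants of the geometry tables, one pair (lMT, J) per muscle.
## Natural splines keep the extrapolation mild; callers should stay within
## the tabulated angle range.
geometry_interpolants <- function(model) {
  lapply(model$geometry, function(g) {
    list(
      lMT = splinefun(g$phi_deg, g$lMT_m, method = "natural"),
      J = splinefun(g$phi_deg, g$moment_arm_m, method = "natural")
    )
  })
}

#' Check moment-arm / length consistency of the geometry tables
#'
#' The moment arm must equal the negative derivative of the musculotendon
#' length with respect to the elbow angle in radians,
#' `J(phi) = -d lMT / d phi_rad`. The derivative is taken from the cubic
#' interpolant of the length table and compared at interior grid points.
#'
#' @param model a [msk_model()].
#' @param tol maximum allowed relative error (default 0.02).
#' @return invisibly, a named numeric vector of worst relative errors per
#'   muscle; disagreement beyond `tol` raises an error.
#' @export
check_geometry_consistency <- function(model, tol = 0.02) {
  worst <- vapply(model$muscles$name, function(nm) {
    g <- model$geometry[[nm]]
    sf <- splinefun(g$phi_deg, g$lMT_m, method = "natural")
    idx <- seq(2, length(g$phi_deg) - 1)
    d <- -sf(g$phi_deg[idx], deriv = 1) * 180 / pi   # per radian
    rel <- abs(d - g$moment_arm_m[idx]) / pmax(abs(g$moment_arm_m[idx]), 1e-9)
    max(rel)
  }, numeric(1))
  bad <- names(worst)[worst > tol]
  if (length(bad)) {
    stop(sprintf("moment arm inconsistent with length derivative for: %s (worst rel. error %.3f)",
                 paste(bad, collapse = ", "), max(worst)))
  }
  invisible(worst)
}

#' Scale length parameters to a subject
#'
#' Scales each muscle's optimal fiber length and tendon slack length by the
#' ratio of the subject's outstretched-arm musculotendon length to the
#' reference model's, `s = subject_lMT0 / reference_lMT0`. All other
#' parameters are unchanged.
#'
#' @param model a [msk_model()].
#' @param subject_lMT0 named numeric vector (or scalar) of subject
#'   musculotendon lengths with outstretched arm (m, > 0), per muscle.
#' @param reference_lMT0 matching reference lengths (m, > 0).
#' @return the scaled model.
#' @export
scale_length_parameters <- function(model, subject_lMT0, reference_lMT0) {
  nms <- model$muscles$name
  subj <- if (length(subject_lMT0) == 1) stats::setNames(rep(subject_lMT0, length(nms)), nms) else subject_lMT0[nms]
  ref <- if (length(reference_lMT0) == 1) stats::setNames(rep(reference_lMT0, length(nms)), nms) else reference_lMT0[nms]
  bad <- nms[is.na(subj) | is.na(ref) | subj <= 0 | ref <= 0]
  if (length(bad)) {
    stop(sprintf("non-positive or missing reference length for muscle(s): %s",
                 paste(bad, collapse = ", ")))
  }
  s <- subj / ref
  model$muscles$l0M <- model$muscles$l0M * s
  model$muscles$lST <- model$muscles$lST * s
  model
}

#' Aggregate a multi-muscle model into joint-level actuators
#'
#' Collapses a 7-muscle model to one flexor and one extensor actuator (2M).
#' For each side the optimal fiber length, tendon slack length, pennation
#' angle and fatigue parameters are arithmetic means across the side's
#' muscles, while the maximum isometric force is the sum. Geometry functions
#' are averaged pointwise on the first muscle's angle grid.
#'
#' @param model a 7M [msk_model()].
#' @return a 2M model with muscles `"flexor"` and `"extensor"`.
#' @export
aggregate_to_joint_actuators <- function(model) {
  if (model$variant != "7M") {
    stop(sprintf("aggregation expects a 7M model, got %s", model$variant))
  }
  agg_side <- function(role) {
    idx <- which(model$muscles$role == role)
    if (!length(idx)) stop(sprintf("model has no %s muscles", role))
    m <- model$muscles[idx, ]
    phi <- model$geometry[[m$name[1]]]$phi_deg
    lMT <- rowMeans(vapply(m$name, function(nm) {
      g <- model$geometry[[nm]]
      splinefun(g$phi_deg, g$lMT_m, method = "natural")(phi)
    }, numeric(length(phi))))
    J <- rowMeans(vapply(m$name, function(nm) {
      g <- model$geometry[[nm]]
      splinefun(g$phi_deg, g$moment_arm_m, method = "natural")(phi)
    }, numeric(length(phi))))
    list(
      muscle = muscle_table(
        name = role, role = role,
        F0M = sum(m$F0M), l0M = mean(m$l0M), lST = mean(m$lST),
        alpha0 = mean(m$alpha0), fiber_group = "undivided",
        F = mean(m$F), R = mean(m$R), r_rest = mean(m$r_rest)
      ),
      geometry = list(phi_deg = phi, lMT_m = lMT, moment_arm_m = J)
    )
  }
  fl <- agg_side("flexor")
  ex <- agg_side("extensor")
  msk_model(
    muscles = rbind(fl$muscle, ex$muscle),
    geometry = list(flexor = fl$geometry, extensor = ex$geometry),
    variant = "2M", curves = model$curves
  )
}

#' Split each muscle into fiber-type groups
#'
#' Expands a 7M model into a 14M model in which every muscle is represented
#' by a fatigue-resistant group A (type I + IIa fibers) and a fast-fatigable
#' group B (type IIx). The maximum isometric force is apportioned from the
#' percentage of force decay observed in a sustained maximal effort: 90% of
#' that decay is attributed to group B, so
#' `F0M_A = F0M * (100 - pct_decay * 0.9) / 100` and
#' `F0M_B = F0M * (pct_decay * 0.9) / 100`; the two parts always sum to the
#' original `F0M`. Geometry is shared between the two groups of a muscle.
#'
#' @param model a 7M [msk_model()].
#' @param pct_decay percentage of force decay (0-100) measured during a
#'   sustained maximal contraction (see [compute_pct_decay()]).
#' @param groupA_fatigue,groupB_fatigue [fatigue_params()] attached to every
#'   group-A / group-B entry.
#' @param group_b_share fraction of the decay attributed to group B
#'   (default 0.9).
#' @return a 14M model with muscles suffixed `_A` and `_B`.
#' @export
split_fiber_types <- function(model, pct_decay,
                              groupA_fatigue = fatigue_params(0.004, 0.01, 1),
                              groupB_fatigue = fatigue_params(0.1, 0.001, 10),
                              group_b_share = 0.9) {
  if (model$variant != "7M") {
    stop(sprintf("fiber-type splitting expects a 7M model, got %s", model$variant))
  }
  if (pct_decay < 0 || pct_decay > 100) {
    stop("pct_decay must be between 0 and 100")
  }
  share_b <- pct_decay * group_b_share / 100
  rows <- list(); geom <- list()
  for (i in seq_len(nrow(model$muscles))) {
    m <- model$muscles[i, ]
    g <- model$geometry[[m$name]]
    for (grp in c("A", "B")) {
      fat <- if (grp == "A") groupA_fatigue else groupB_fatigue
      f0 <- if (grp == "A") m$F0M * (1 - share_b) else m$F0M * share_b
      nm <- paste0(m$name, "_", grp)
      rows[[nm]] <- muscle_table(
        name = nm, role = m$role, F0M = f0, l0M = m$l0M, lST = m$lST,
        alpha0 = m$alpha0, fiber_group = grp,
        F = fat$F, R = fat$R, r_rest = fat$r_rest
      )
      geom[[nm]] <- g
    }
  }
  muscles <- do.call(rbind, rows)
  rownames(muscles) <- NULL
  msk_model(muscles = muscles, geometry = geom, variant = "14M",
            curves = model$curves)
}
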