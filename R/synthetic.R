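## Synthetic data generators: toy elbow models, hammer-curl kinematics and
## torques, and MVC strain-gauge traces with known fatigue parameters. All
## generators are pure functions of their parameters and seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy elbow musculoskeletal model
#'
#' Builds a deterministic multi-muscle elbow model with physiologically
#' plausible parameters and internally consistent geometry. Flexor moment
#' arms peak in mid-flexion; extensor arms are negative and nearly constant.
#' Musculotendon length tables are obtained analytically from
#' `lMT(phi) = lMT(0) - integral of J d(phi_rad)`, so the moment-arm /
#' length-derivative consistency holds by construction. Moment-arm
#' magnitudes scale with each muscle's optimal fiber length so normalized
#' fiber lengths stay within the active force-length curve's support over
#' the full 0-150 deg range.
#'
#' @param n_flexors,n_extensors number of muscles per side (>= 1); the
#'   default 4 + 3 mirrors a 7-muscle elbow model.
#' @param seed RNG seed.
#' @param phi_grid_deg tabulation grid (deg), default `seq(0, 150, 5)`.
#' @return a 7M-variant [msk_model()] (tagged `"7M"` regardless of counts).
#' @export
#' @examples
#' mdl <- make_toy_elbow_model(seed = 1)
#' check_geometry_consistency(mdl)
make_toy_elbow_model <- function(n_flexors = 4, n_extensors = 3, seed = 1,
                                 phi_grid_deg = seq(0, 150, 5)) {
  stopifnot(n_flexors >= 1, n_extensors >= 1)
  with_seed(seed, {
    flex_names <- c("biceps_long", "biceps_short", "brachialis",
                    "brachioradialis",
                    paste0("flexor_", seq_len(max(0, n_flexors - 4)) + 4))[seq_len(n_flexors)]
    ext_names <- c("triceps_long", "triceps_medial", "triceps_lateral",
                   paste0("extensor_", seq_len(max(0, n_extensors - 3)) + 3))[seq_len(n_extensors)]
    phi <- phi_grid_deg
    rad <- pi / 180
    rows <- list(); geom <- list()
    make_muscle <- function(nm, role) {
      F0M <- runif(1, 200, 800)
      l0M <- runif(1, 0.06, 0.16)
      lST <- l0M * runif(1, 1.2, 2.0)
      alpha0 <- runif(1, 0, 0.25)
      if (role == "flexor") {
        Jp <- 0.30 * l0M * runif(1, 0.9, 1.1)
        J <- Jp * (0.6 + 0.4 * cos((phi - 70) * rad))
        ## antiderivative of J wrt phi in radians
        S <- Jp * (0.6 * phi * rad + 0.4 * (sin((phi - 70) * rad) - sin(-70 * rad)))
        h <- l0M * sin(alpha0)
        lMT0 <- lST + sqrt((1.25 * l0M)^2 - h^2)
        lMT <- lMT0 - S
      } else {
        Je <- 0.20 * l0M * runif(1, 0.9, 1.1)
        J <- -Je * (0.9 + 0.1 * cos(phi * rad))
        S <- Je * (0.9 * phi * rad + 0.1 * sin(phi * rad))
        h <- l0M * sin(alpha0)
        lMT0 <- lST + sqrt((0.75 * l0M)^2 - h^2)
        lMT <- lMT0 + S
      }
      rows[[nm]] <<- muscle_table(nm, role, F0M, l0M, lST, alpha0)
      geom[[nm]] <<- list(phi_deg = phi, lMT_m = lMT, moment_arm_m = J)
    }
    for (nm in flex_names) make_muscle(nm, "flexor")
    for (nm in ext_names) make_muscle(nm, "extensor")
    muscles <- do.call(rbind, rows)
    rownames(muscles) <- NULL
    msk_model(muscles, geom, variant = "7M")
  })
}

#' Construct a synthetic subject
#'
#' Bundles a toy elbow model with "true" fatigue parameters (used by the
#' trace generators and recoverable by the calibration fits), forearm
#' inertial parameters and a dumbbell mass chosen so the gravitational
#' demand at the MVC posture equals a set fraction of the rested maximal
#' flexion moment.
#'
#' @param seed RNG seed; the model and all derived quantities are
#'   reproducible given the seed.
#' @param n_flexors,n_extensors muscle counts, see [make_toy_elbow_model()].
#' @param fatigue_true subject-level "true" [fatigue_params()] used when
#'   generating MVC traces (default `F = 0.01`, `R = 0.005`,
#'   `r_rest = 15`).
#' @param groupA_fatigue,groupB_fatigue true per-group parameters for
#'   fiber-type (14M) trace generation.
#' @param load_fraction dumbbell demand as a fraction of the rested maximal
#'   flexion moment at the MVC posture (default 0.65).
#' @param mvc_phi_deg MVC / static-hold posture (deg, default 50).
#' @return object of class `synthetic_subject`: list with `model`,
#'   `fatigue_true`, `groupA_fatigue`, `groupB_fatigue`, `dumbbell_mass_kg`,
#'   `forearm_mass_kg`, `forearm_com_m`, `forearm_inertia_kgm2`,
#'   `forearm_length_m`, `mvc_phi_deg`, `seed`.
#' @export
synthetic_subject <- function(seed = 1, n_flexors = 4, n_extensors = 3,
                              fatigue_true = fatigue_params(0.01, 0.005, 15),
                              groupA_fatigue = fatigue_params(0.004, 0.01, 1),
                              groupB_fatigue = fatigue_params(0.1, 0.001, 10),
                              load_fraction = 0.65, mvc_phi_deg = 50) {
  model <- make_toy_elbow_model(n_flexors, n_extensors, seed)
  model$muscles$F <- fatigue_true$F
  model$muscles$R <- fatigue_true$R
  model$muscles$r_rest <- fatigue_true$r_rest
  forearm_mass <- 0.022 * 80          # forearm+hand mass, 80 kg subject
  forearm_length <- 0.30
  forearm_com <- 0.45 * forearm_length
  forearm_inertia <- forearm_mass * (0.27 * forearm_length)^2
  Qcap <- available_max_moment(model, mvc_phi_deg)
  g <- 9.81
  ## dumbbell mass such that the gravitational demand at the MVC posture is
  ## load_fraction of capacity (forearm weight included in the demand)
  sin_phi <- sin(mvc_phi_deg * pi / 180)
  md <- (load_fraction * Qcap / (g * sin_phi) - forearm_mass * forearm_com) /
    forearm_length
  if (md <= 0) stop("load fraction too small for the forearm weight alone")
  structure(
    list(
      model = model, fatigue_true = fatigue_true,
      groupA_fatigue = groupA_fatigue, groupB_fatigue = groupB_fatigue,
      dumbbell_mass_kg = md, forearm_mass_kg = forearm_mass,
      forearm_com_m = forearm_com, forearm_inertia_kgm2 = forearm_inertia,
      forearm_length_m = forearm_length, mvc_phi_deg = mvc_phi_deg,
      seed = seed
    ),
    class = "synthetic_subject"
  )
}

#' Gravitational elbow torque of a held dumbbell
#'
#' Planar model with the upper arm vertical: the forearm makes an angle
#' `phi - 90` deg with the horizontal, so the gravitational flexion torque
#' is `(m_f * d_f + m_d * L) * g * sin(phi)`.
#'
#' @param phi_deg elbow flexion angle (deg; 0 = full extension).
#' @param mass_kg dumbbell mass (kg).
#' @param subject subject parameters (see [synthetic_subject()] /
#'   [protocol()]).
#' @return flexion torque (N*m).
#' @export
gravitational_torque <- function(phi_deg, mass_kg, subject) {
  g <- 9.81
  (subject$forearm_mass_kg * subject$forearm_com_m +
     mass_kg * subject$forearm_length_m) * g * sin(phi_deg * pi / 180)
}

#' Generate hammer-curl kinematics and torques
#'
#' The elbow angle follows a raised cosine between the range endpoints with
#' one full flexion-extension cycle per repetition. The net flexion torque
#' comes from planar forearm dynamics,
#' `Q = (I + m_d L^2) * phiddot_rad + (m_f d_f + m_d L) * g * cos(theta_h)`,
#' with `theta_h = phi - 90` deg the forearm angle from the horizontal
#' (upper arm vertical).
#'
#' @param reps number of repetitions.
#' @param period_s seconds per repetition.
#' @param phi_range_deg `c(min, max)` elbow angle sweep (deg).
#' @param subject subject parameters (forearm inertia/mass/COM/length; see
#'   [synthetic_subject()]).
#' @param mass_kg dumbbell mass; defaults to the subject's dumbbell.
#' @param dt sample interval (s, default 0.01).
#' @return data frame of joint samples: `t_s`, `phi_deg`, `phidot_deg_s`,
#'   `Q_Nm`.
#' @export
generate_curl_motion <- function(reps, period_s, phi_range_deg = c(30, 130),
                                 subject, mass_kg = NULL, dt = 0.01) {
  stopifnot(period_s > 0, reps >= 1)
  if (is.null(mass_kg)) mass_kg <- subject$dumbbell_mass_kg
  t <- seq(0, reps * period_s, by = dt)
  lo <- phi_range_deg[1]; hi <- phi_range_deg[2]
  w <- 2 * pi / period_s
  phi <- lo + (hi - lo) * (1 - cos(w * t)) / 2
  phidot <- (hi - lo) / 2 * w * sin(w * t)                 # deg/s
  phiddot_rad <- (hi - lo) / 2 * w^2 * cos(w * t) * pi / 180
  g <- 9.81
  I_tot <- subject$forearm_inertia_kgm2 +
    mass_kg * subject$forearm_length_m^2
  static_arm <- subject$forearm_mass_kg * subject$forearm_com_m +
    mass_kg * subject$forearm_length_m
  Q <- I_tot * phiddot_rad + static_arm * g * sin(phi * pi / 180)
  data.frame(t_s = t, phi_deg = phi, phidot_deg_s = phidot, Q_Nm = Q)
}

#' Generate a synthetic MVC strain-gauge force trace
#'
#' Simulates the force recorded by a gauge in series with a rope pulled at
#' the MVC posture: the rested maximal flexion moment divided by the forearm
#' (lever) length, decayed over time by the subject's true 3CCr parameters
#' at a 100% target load, plus i.i.d. Gaussian noise. With `two_group =
#' TRUE` the decay is the F0-weighted sum of the fiber-type groups' active
#' compartments (the fiber-split forward model).
#'
#' @param subject a [synthetic_subject()].
#' @param duration_s effort duration (s).
#' @param noise_sd_pct noise standard deviation, percent of the baseline
#'   maximum (default 0).
#' @param seed RNG seed for the noise.
#' @param fs sampling rate (Hz, default 100).
#' @param two_group simulate a two-fiber-group subject (default FALSE).
#' @param pct_decay force-decay percentage used for the group split when
#'   `two_group = TRUE` (default 20).
#' @return data frame with `t_s`, `force_N`.
#' @export
generate_mvc_trace <- function(subject, duration_s, noise_sd_pct = 0,
                               seed = 1, fs = 100, two_group = FALSE,
                               pct_decay = 20) {
  baseline <- available_max_moment(subject$model, subject$mvc_phi_deg) /
    subject$forearm_length_m
  t <- seq(0, duration_s, by = 1 / fs)
  if (two_group) {
    shareB <- pct_decay * 0.9 / 100
    trajA <- ccr_simulate(100, subject$groupA_fatigue, duration_s, dt = 0.01)
    trajB <- ccr_simulate(100, subject$groupB_fatigue, duration_s, dt = 0.01)
    fA <- approx(trajA$t_s, trajA$Ma, xout = t, rule = 2)$y
    fB <- approx(trajB$t_s, trajB$Ma, xout = t, rule = 2)$y
    force <- baseline * ((1 - shareB) * fA + shareB * fB) / 100
  } else {
    traj <- ccr_simulate(100, subject$fatigue_true, duration_s, dt = 0.01)
    force <- baseline * approx(traj$t_s, traj$Ma, xout = t, rule = 2)$y / 100
  }
  if (noise_sd_pct > 0) {
    force <- force + with_seed(seed, rnorm(length(t), 0,
                                           noise_sd_pct / 100 * baseline))
  }
  data.frame(t_s = t, force_N = force)
}

#' Generate a calibration pair of MVC traces
#'
#' Produces the two traces the fatigue-parameter fit consumes, on a shared
#' clock: a sustained maximal effort (identifying the fatigue rate) and a
#' short maximal probe after a rest (identifying the recovery rate and rest
#' multiplier). Forces are generated from the subject's true 3CCr
#' parameters and normalized to the baseline maximum, with optional
#' Gaussian gauge noise.
#'
#' @param subject a [synthetic_subject()].
#' @param decay_s sustained-effort duration (s, default 60).
#' @param rest_s rest gap before the probe (s, default 15).
#' @param probe_s probe duration (s, default 6).
#' @param noise_sd_pct noise SD, percent of baseline maximum (default 0).
#' @param seed RNG seed for the noise.
#' @param fs sampling rate (Hz, default 100).
#' @param two_group,pct_decay see [generate_mvc_trace()].
#' @return list with `decay` and `probe` data frames (`t_s`, `force_norm`)
#'   on a shared clock.
#' @export
generate_mvc_pair <- function(subject, decay_s = 60, rest_s = 15,
                              probe_s = 6, noise_sd_pct = 0, seed = 1,
                              fs = 100, two_group = FALSE, pct_decay = 20) {
  dt <- 0.01
  horizon <- decay_s + rest_s + probe_s
  tl_fn <- function(t) if (t < decay_s || t >= decay_s + rest_s) 100 else 0
  norm_force <- function(params, share = 1) {
    traj <- ccr_simulate(tl_fn, params, horizon, dt = dt)
    share * traj$Ma / 100
  }
  if (two_group) {
    shareB <- pct_decay * 0.9 / 100
    f <- norm_force(subject$groupA_fatigue, 1 - shareB) +
      norm_force(subject$groupB_fatigue, shareB)
  } else {
    f <- norm_force(subject$fatigue_true)
  }
  t_all <- seq(0, horizon, by = dt)
  pick <- function(t0, t1) {
    idx <- which(t_all >= t0 & t_all <= t1)
    idx <- idx[seq(1, length(idx), by = max(1L, round(1 / (fs * dt))))]
    data.frame(t_s = t_all[idx], force_norm = f[idx])
  }
  decay <- pick(0, decay_s)
  probe <- pick(decay_s + rest_s, horizon)
  if (noise_sd_pct > 0) {
    with_seed(seed, {
      decay$force_norm <- decay$force_norm +
        rnorm(nrow(decay), 0, noise_sd_pct / 100)
      probe$force_norm <- probe$force_norm +
        rnorm(nrow(probe), 0, noise_sd_pct / 100)
    })
  }
  list(decay = decay, probe = probe)
}

#' Generate a complete benchmark session fixture
#'
#' Writes to `dir` the inputs of a full training-session benchmark: the
#' model YAML, a protocol YAML (baseline MVC triplet of 8 s, to-failure and
#' 6 s efforts separated by 15 s rests; then 3 cycles of 3 sets of 10
#' hammer-curl repetitions with 90 s rests, an MVC triplet after each
#' cycle), a hammer-curl motion CSV for one set, and noisy MVC gauge traces.
#' The dumbbell demand is the subject's `load_fraction` (default 65%) of
#' rested capacity at the MVC posture.
#'
#' @param subject a [synthetic_subject()].
#' @param dir output directory (created if missing).
#' @param mvc0_fail_s duration standing in for the to-failure baseline
#'   effort (s, default 60).
#' @param noise_sd_pct gauge noise level for the MVC traces (default 2).
#' @return (invisibly) named list of written file paths.
#' @export
generate_session_fixture <- function(subject, dir, mvc0_fail_s = 60,
                                     noise_sd_pct = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phi <- subject$mvc_phi_deg
  mvc_triplet <- function(d1, d2, d3) {
    list(
      list(kind = "mvc", duration_s = d1, phi_deg = phi),
      list(kind = "rest", duration_s = 15, phi_deg = phi),
      list(kind = "mvc", duration_s = d2, phi_deg = phi),
      list(kind = "rest", duration_s = 15, phi_deg = phi),
      list(kind = "mvc", duration_s = d3, phi_deg = phi)
    )
  }
  segments <- mvc_triplet(8, mvc0_fail_s, 6)
  for (cycle in 1:3) {
    for (set in 1:3) {
      segments <- c(segments, list(
        list(kind = "curl_set", reps = 10, cadence_s = 3,
             mass_kg = subject$dumbbell_mass_kg,
             phi_range_deg = c(30, 130)),
        list(kind = "rest", duration_s = 90, phi_deg = phi)
      ))
    }
    trip <- mvc_triplet(8, 8, 8)
    trip[[5]]$cycle <- cycle
    segments <- c(segments, trip)
  }
  prot <- protocol(segments, subject = subject[c(
    "forearm_mass_kg", "forearm_com_m", "forearm_inertia_kgm2",
    "forearm_length_m"
  )])
  paths <- list(
    model = file.path(dir, "model.yaml"),
    protocol = file.path(dir, "protocol.yaml"),
    motion = file.path(dir, "curl_set_motion.csv"),
    mvc0_2 = file.path(dir, "mvc0_2_trace.csv"),
    mvc0_3 = file.path(dir, "mvc0_3_trace.csv")
  )
  write_model_yaml(subject$model, paths$model)
  write_protocol_yaml(prot, paths$protocol)
  write_motion_csv(
    generate_curl_motion(10, 3, c(30, 130), subject),
    paths$motion
  )
  write_trace_csv(
    generate_mvc_trace(subject, mvc0_fail_s, noise_sd_pct, seed = subject$seed),
    paths$mvc0_2
  )
  write_trace_csv(
    generate_mvc_trace(subject, 6, noise_sd_pct, seed = subject$seed + 1),
    paths$mvc0_3
  )
  invisible(paths)
}
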