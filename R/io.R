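## File formats and preprocessing: model and protocol YAML, motion and trace
## CSV, session results, EMG envelope. All angles in files are degrees; all
## CSVs are comma-separated UTF-8 with a header row and '.' decimals.

.check_fields <- function(x, required, optional, where) {
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("%s: missing required field(s): %s", where,
                 paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown)) {
    warning(sprintf("%s: unknown field(s) ignored: %s", where,
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

#' Write a musculoskeletal model to YAML
#'
#' Per-muscle blocks carry `name`, `role`, `F0M_N`, `l0M_m`, `lST_m`,
#' `alpha0_deg`, `fiber_group` and a `fatigue` block (`F_per_s`, `R_per_s`,
#' `r_rest`); geometry tables carry `phi_deg`, `lMT_m`, `moment_arm_m`.
#'
#' @param model a [msk_model()].
#' @param path output file path.
#' @return (invisibly) `path`.
#' @export
write_model_yaml <- function(model, path) {
  mus <- lapply(seq_len(nrow(model$muscles)), function(i) {
    m <- model$muscles[i, ]
    g <- model$geometry[[m$name]]
    list(
      name = m$name, role = m$role,
      F0M_N = m$F0M, l0M_m = m$l0M, lST_m = m$lST,
      alpha0_deg = m$alpha0 * 180 / pi,
      fiber_group = m$fiber_group,
      fatigue = list(F_per_s = m$F, R_per_s = m$R, r_rest = m$r_rest),
      geometry = list(
        phi_deg = as.numeric(g$phi_deg),
        lMT_m = as.numeric(g$lMT_m),
        moment_arm_m = as.numeric(g$moment_arm_m)
      )
    )
  })
  obj <- list(variant = model$variant, hill_curves = model$curves,
              muscles = mus)
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Read a musculoskeletal model from YAML
#'
#' @param path YAML file written by [write_model_yaml()] (or conforming to
#'   its schema).
#' @return a [msk_model()].
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  .check_fields(obj, c("variant", "muscles"), "hill_curves", path)
  rows <- list(); geom <- list()
  for (mu in obj$muscles) {
    .check_fields(mu, c("name", "role", "F0M_N", "l0M_m", "lST_m",
                        "alpha0_deg", "fiber_group", "fatigue", "geometry"),
                  character(0), sprintf("%s: muscle '%s'", path,
                                        mu$name %||% "?"))
    .check_fields(mu$fatigue, c("F_per_s", "R_per_s", "r_rest"),
                  character(0), sprintf("muscle '%s' fatigue", mu$name))
    .check_fields(mu$geometry, c("phi_deg", "lMT_m", "moment_arm_m"),
                  character(0), sprintf("muscle '%s' geometry", mu$name))
    rows[[mu$name]] <- muscle_table(
      mu$name, mu$role, mu$F0M_N, mu$l0M_m, mu$lST_m,
      mu$alpha0_deg * pi / 180, mu$fiber_group,
      F = mu$fatigue$F_per_s, R = mu$fatigue$R_per_s,
      r_rest = mu$fatigue$r_rest
    )
    geom[[mu$name]] <- list(
      phi_deg = as.numeric(mu$geometry$phi_deg),
      lMT_m = as.numeric(mu$geometry$lMT_m),
      moment_arm_m = as.numeric(mu$geometry$moment_arm_m)
    )
  }
  muscles <- do.call(rbind, rows)
  rownames(muscles) <- NULL
  msk_model(muscles, geom, variant = obj$variant, curves = obj$hill_curves)
}

#' Write / read a task protocol YAML
#'
#' @param prot a [protocol()].
#' @param path file path.
#' @return (invisibly) `path` / a [protocol()].
#' @export
write_protocol_yaml <- function(prot, path) {
  yaml::write_yaml(list(subject = prot$subject, segments = prot$segments),
                   path, precision = 12)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  .check_fields(obj, "segments", "subject", path)
  protocol(obj$segments, subject = obj$subject)
}

.read_timeseries_csv <- function(path, required) {
  df <- read.csv(path)
  .check_fields(df, required, setdiff(names(df), required), path)
  if (any(!is.finite(as.matrix(df[required])))) {
    stop(sprintf("%s: missing or non-finite values", path))
  }
  if (any(diff(df$t_s) <= 0)) {
    stop(sprintf("%s: t_s must be strictly increasing", path))
  }
  df
}

#' Motion and force-trace CSV I/O
#'
#' Motion files have columns `t_s`, `phi_deg`, `phidot_deg_s`, `Q_Nm`;
#' force traces have `t_s`, `force_N`. `t_s` must be strictly increasing
#' and all values finite.
#'
#' @param motion,trace data frames to write.
#' @param path file path.
#' @return (invisibly) `path` for writers; the validated data frame for
#'   readers.
#' @export
write_motion_csv <- function(motion, path) {
  write.csv(motion[c("t_s", "phi_deg", "phidot_deg_s", "Q_Nm")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path) {
  .read_timeseries_csv(path, c("t_s", "phi_deg", "phidot_deg_s", "Q_Nm"))
}

#' @rdname write_motion_csv
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace[c("t_s", "force_N")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_trace_csv <- function(path) {
  .read_timeseries_csv(path, c("t_s", "force_N"))
}

#' Write session results
#'
#' The long-format CSV has one row per time step and muscle (`t_s`,
#' `muscle`, `force_N`, `activation`, `Ma`, `Mr`, `Mf`); the summary JSON
#' carries failure events, the equilibrium flag and per-segment torque
#' residual maxima.
#'
#' @param result a `session_result` from [simulate_protocol()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return (invisibly) list of written paths.
#' @export
write_session_result <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    n <- nrow(result$timeseries); m <- length(result$muscles)
    long <- data.frame(
      t_s = rep(result$timeseries$t_s, times = m),
      muscle = rep(result$muscles, each = n),
      force_N = as.vector(result$forces_N),
      activation = as.vector(result$activations),
      Ma = as.vector(result$Ma), Mr = as.vector(result$Mr),
      Mf = as.vector(result$Mf)
    )
    write.csv(long, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summary <- list(
      duration_s = max(result$timeseries$t_s),
      n_muscles = length(result$muscles),
      first_torque_deficit_s = if (nrow(result$events$failures)) {
        min(result$events$failures$t_s)
      } else NULL,
      max_torque_residual_Nm = max(result$timeseries$torque_residual_Nm),
      equilibrium = result$events$equilibrium,
      cycle_delta_Mf = result$events$cycle_delta_Mf,
      final_Mf = stats::setNames(as.list(tail(result$Mf, 1)[1, ]),
                                 result$muscles)
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' EMG envelope preprocessing
#'
#' Full-wave rectification followed by zero-phase (forward and reverse)
#' fifth-order Butterworth low-pass filtering at 6 Hz, then normalization by
#' the maximum envelope value observed during the reference MVC. Zero-phase
#' filtering introduces no lag, and the filter's unit DC gain preserves
#' sustained amplitude.
#'
#' @param raw data frame with `t_s` and one signal column (the first
#'   non-time column is used), uniformly sampled.
#' @param mvc_reference_max normalization constant: maximum envelope value
#'   during the reference MVC (> 0), in the raw signal's units.
#' @param cutoff_hz low-pass cutoff (Hz, default 6).
#' @param order filter order (default 5).
#' @return data frame with `t_s` and `envelope` (dimensionless).
#' @export
emg_envelope <- function(raw, mvc_reference_max, cutoff_hz = 6, order = 5) {
  if (mvc_reference_max <= 0) stop("MVC reference maximum must be positive")
  sig_col <- setdiff(names(raw), "t_s")[1]
  dtm <- diff(raw$t_s)
  if (any(dtm <= 0) || diff(range(dtm)) > 1e-9 * mean(dtm)) {
    stop("raw EMG must be uniformly sampled with strictly increasing t_s")
  }
  fs <- 1 / mean(dtm)
  rect <- abs(raw[[sig_col]])
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  env <- signal::filtfilt(bf, rect)
  data.frame(t_s = raw$t_s, envelope = env / mvc_reference_max)
}
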