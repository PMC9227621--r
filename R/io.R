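# Plain-text interchange formats: trajectory, passive-trial and EMG CSVs
# ('.' decimal, mandatory headers) and the subject-parameter YAML.

#' Write a wrist trajectory to CSV
#'
#' Columns: `time_s`, `beta_rad`, `gamma_rad`, `beta_dot`, `gamma_dot`,
#' `beta_ddot`, `gamma_ddot`, `T_beta_Nm`, `T_gamma_Nm`.
#'
#' @param traj a `wrist_trajectory` (see [forward_simulate()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  need <- c("time_s", "beta_rad", "gamma_rad", "beta_dot", "gamma_dot",
            "beta_ddot", "gamma_ddot", "T_beta_Nm", "T_gamma_Nm")
  stopifnot(all(need %in% names(df)))
  utils::write.csv(df[need], path, row.names = FALSE)
  invisible(path)
}

#' Read a wrist trajectory from CSV
#'
#' @param path file written by [write_trajectory_csv()] (or equivalent).
#' @return A `wrist_trajectory` data frame.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "beta_rad", "gamma_rad", "beta_dot", "gamma_dot")
  if (!all(need %in% names(df))) {
    stop("read_trajectory_csv: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("read_trajectory_csv: time_s must be strictly increasing",
         call. = FALSE)
  }
  class(df) <- c("wrist_trajectory", "data.frame")
  df
}

#' Write a passive trial to CSV
#'
#' Columns: `direction`, `displacement_rad`, `torque_main_Nm` and (when
#' recorded) `torque_cross_Nm`.
#'
#' @param trial a [passive_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_passive_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "passive_trial"))
  df <- data.frame(direction = trial$direction,
                   displacement_rad = trial$displacements,
                   torque_main_Nm = trial$torques_main)
  if (!is.null(trial$torques_cross)) {
    df$torque_cross_Nm <- trial$torques_cross
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a passive trial from CSV
#'
#' @param path file written by [write_passive_trial_csv()].
#' @return A [passive_trial()].
#' @export
read_passive_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("direction", "displacement_rad", "torque_main_Nm")
  if (!all(need %in% names(df))) {
    stop("read_passive_trial_csv: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  passive_trial(df$direction[1], df$displacement_rad, df$torque_main_Nm,
                if ("torque_cross_Nm" %in% names(df)) df$torque_cross_Nm)
}

#' Write an EMG record to CSV
#'
#' Columns `time_s`, `emg_mV`; the sampling rate is recoverable from the
#' time column.
#'
#' @param rec an [emg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_record"))
  utils::write.csv(
    data.frame(time_s = (seq_along(rec$samples) - 1) / rec$fs,
               emg_mV = rec$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an EMG record from CSV
#'
#' @param path file with columns `time_s`, `emg_mV`.
#' @param fs sampling rate (Hz); if `NULL`, inferred from the median time
#'   step.
#' @return An [emg_record()].
#' @export
read_emg_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "emg_mV") %in% names(df))) {
    stop("read_emg_csv: expected columns time_s, emg_mV", call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time_s))
  emg_record(df$emg_mV, fs)
}

#' Write subject parameters (inertial + tensors) to YAML
#'
#' @param params an [inertial_params()].
#' @param K a [stiffness_tensor()] or `NULL`.
#' @param B a [damping_tensor()] or `NULL`.
#' @param path output path.
#' @param subject_id subject label stored in the file.
#' @return `path`, invisibly.
#' @export
write_subject_params_yaml <- function(params, K = NULL, B = NULL, path,
                                      subject_id = "anonymous") {
  stopifnot(inherits(params, "inertial_params"))
  doc <- list(subject_id = subject_id,
              inertial = unclass(params))
  if (!is.null(K)) doc$stiffness <- unclass(K)
  if (!is.null(B)) doc$damping <- unclass(B)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read subject parameters from YAML
#'
#' @param path file written by [write_subject_params_yaml()].
#' @return List with `subject_id`, `params` ([inertial_params()]) and,
#'   when present, `K` and `B`.
#' @export
read_subject_params_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  ip <- doc$inertial
  out <- list(
    subject_id = doc$subject_id,
    params = inertial_params(m = ip$m, Ix = ip$Ix, Iy = ip$Iy, Iz = ip$Iz,
                             rCD = ip$rCD, Iw = ip$Iw, rAC = ip$rAC,
                             g = ip$g))
  if (!is.null(doc$stiffness)) {
    out$K <- stiffness_tensor(doc$stiffness$Kbb, doc$stiffness$Kbg,
                              doc$stiffness$Kgg)
  }
  if (!is.null(doc$damping)) {
    out$B <- damping_tensor(doc$damping$Bbb, doc$damping$Bbg,
                            doc$damping$Bgg)
  }
  out
}
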