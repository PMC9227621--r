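#' Protocol phases
#'
#' The three phases of the rehabilitation protocol, in their enforced
#' order: the robot moves the fully passive patient (parameter
#' identification), the patient works against a resistive robot (active
#' capacity measurement), then both contribute torque (assist-as-needed
#' exercise). A patient who cannot produce readable torque in the
#' resistive phase is routed back to passive exercise instead of
#' progressing.
#'
#' @return Character vector of the phase names in order.
#' @export
protocol_phases <- function() {
  c("PASSIVE_ROBOT_ACTIVE", "PATIENT_ACTIVE_ROBOT_RESISTIVE", "BOTH_ACTIVE")
}

#' Session configuration
#'
#' Central collection of protocol tunables, all overridable.
#'
#' @param movement exercised movement, `"FE"` or `"RUD"`.
#' @param passive_amplitude,passive_speed passive ramp amplitude (rad) and
#'   speed (rad/s).
#' @param passive_noise_sd torque measurement noise in passive trials (Nm).
#' @param passive_tol relative change of `Kbb` and `Kgg` below which the
#'   passive iterations are converged; default 0.02.
#' @param passive_max_iter iteration cap for the passive phase; default 12.
#' @param resistive_torque resistive torque magnitude the robot applies
#'   (Nm).
#' @param readable_threshold minimum peak torque counted as readable (Nm);
#'   default 0.1.
#' @param resistive_duration,combined_duration phase durations (s).
#' @param attenuation_gain gain of the fatigue-to-torque attenuation
#'   mapping; default 1.
#' @param reference_rom healthy-subject reference range of motion used as
#'   the RPF denominator (degrees); default 90.
#' @param dt simulation/log step (s).
#' @param baseline_windows EMG windows defining the fresh baseline.
#' @param allow_combined_override clinician override: allow the combined
#'   phase even without a readable resistive result.
#' @return A list of class `session_config`.
#' @export
session_config <- function(movement = "FE",
                           passive_amplitude = 0.3, passive_speed = 0.1,
                           passive_noise_sd = 0, passive_tol = 0.02,
                           passive_max_iter = 12,
                           resistive_torque = 0.5, readable_threshold = 0.1,
                           resistive_duration = 10, combined_duration = 30,
                           attenuation_gain = 1, reference_rom = 90,
                           dt = 1e-3, baseline_windows = 5,
                           allow_combined_override = FALSE) {
  movement <- match.arg(movement, c("FE", "RUD"))
  structure(list(movement = movement,
                 passive_amplitude = passive_amplitude,
                 passive_speed = passive_speed,
                 passive_noise_sd = passive_noise_sd,
                 passive_tol = passive_tol,
                 passive_max_iter = passive_max_iter,
                 resistive_torque = resistive_torque,
                 readable_threshold = readable_threshold,
                 resistive_duration = resistive_duration,
                 combined_duration = combined_duration,
                 attenuation_gain = attenuation_gain,
                 reference_rom = reference_rom,
                 dt = dt, baseline_windows = baseline_windows,
                 allow_combined_override = allow_combined_override),
            class = "session_config")
}

#' Passive phase: iterative identification of the passive components
#'
#' Repeats slow commanded ramps on the fully passive patient,
#' re-estimating the stiffness tensor from each iteration's FE and RUD
#' trials, until the relative change of both diagonal elements between
#' successive iterations drops below `passive_tol` (default 2%) or the
#' iteration cap is reached. The damping tensor is then constructed by
#' proportional scaling.
#'
#' @param patient a [virtual_patient()], or a function
#'   `f(iteration)` returning `list(fe = , rud = )` of [passive_trial()]s
#'   (e.g. replaying recorded trials).
#' @param config a [session_config()].
#' @return List with `K` ([stiffness_tensor()]), `B`
#'   ([damping_tensor()]), `iterations` used and logical `converged`.
#' @export
run_passive_phase <- function(patient, config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  get_trials <- if (inherits(patient, "virtual_patient")) {
    function(iter) list(
      fe = synth_passive_trial(patient, "FE", config$passive_amplitude,
                               config$passive_speed, config$passive_noise_sd,
                               seed = patient$seed + 101L * iter),
      rud = synth_passive_trial(patient, "RUD", config$passive_amplitude,
                                config$passive_speed, config$passive_noise_sd,
                                seed = patient$seed + 101L * iter + 50L))
  } else if (is.function(patient)) {
    patient
  } else {
    stop("run_passive_phase: patient must be a virtual_patient or a function",
         call. = FALSE)
  }
  K_prev <- NULL
  converged <- FALSE
  iterations <- 0L
  K <- NULL
  for (iter in seq_len(config$passive_max_iter)) {
    iterations <- iter
    tr <- get_trials(iter)
    K <- estimate_stiffness(tr$fe, tr$rud)
    if (!is.null(K_prev)) {
      rel <- c(abs(K$Kbb - K_prev$Kbb) / abs(K_prev$Kbb),
               abs(K$Kgg - K_prev$Kgg) / abs(K_prev$Kgg))
      if (all(rel < config$passive_tol)) {
        converged <- TRUE
        break
      }
    }
    K_prev <- K
  }
  list(K = K, B = build_damping_tensor(K), iterations = iterations,
       converged = converged)
}

#' Resistive phase: measure active torque and achieved range of motion
#'
#' The robot applies a resistive torque while the patient drives the
#' movement; the peak torque the patient produces and the angular
#' excursion they achieve are recorded. A peak below the readable
#' threshold routes the patient back to passive exercise.
#'
#' @param patient a [virtual_patient()] (its effort and excursion scripts
#'   are sampled), or a data frame with columns `time_s`, `angle_rad`,
#'   `torque_Nm` (a recorded log).
#' @param config a [session_config()].
#' @return List with `max_active_torque` (Nm), `rom_deg` (degrees),
#'   logical `readable`, and `next_phase` (the routing decision).
#' @export
run_resistive_phase <- function(patient, config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  if (inherits(patient, "virtual_patient")) {
    times <- seq(0, config$resistive_duration, by = config$dt)
    torque <- patient$effort_script(times)
    angle <- patient$excursion_script(times)
  } else {
    df <- as.data.frame(patient)
    stopifnot(all(c("time_s", "angle_rad", "torque_Nm") %in% names(df)))
    torque <- df$torque_Nm
    angle <- df$angle_rad
  }
  peak <- max(abs(torque))
  rom_deg <- diff(range(angle)) * 180 / pi
  readable <- peak >= config$readable_threshold
  list(max_active_torque = peak, rom_deg = rom_deg, readable = readable,
       next_phase = if (readable) "BOTH_ACTIVE" else "PASSIVE_ROBOT_ACTIVE")
}

#' Fatigue-attenuated patient torque
#'
#' The torque a fatigued patient can actually deliver: the model-based
#' (nominal) torque minus the estimated fatigue torque,
#' `T_fatigue = fatigue_level * attenuation_gain * max_active_torque`.
#' The result is clamped so its magnitude stays in `[0, |model_torque|]`
#' and its sign matches the nominal torque.
#'
#' @param model_torque nominal patient torque (Nm; sign = direction).
#' @param fatigue_level fatigue in `[0, 1]`.
#' @param max_active_torque the patient's measured peak torque (Nm).
#' @param attenuation_gain mapping gain; default 1.
#' @return Deliverable torque (Nm), same sign as `model_torque`.
#' @examples
#' resulting_patient_torque(1.2, 0.5, 1.0)  # 0.7 Nm
#' @export
resulting_patient_torque <- function(model_torque, fatigue_level,
                                     max_active_torque,
                                     attenuation_gain = 1) {
  if (any(!is.finite(c(model_torque, fatigue_level, max_active_torque)))) {
    stop("resulting_patient_torque: inputs must be finite", call. = FALSE)
  }
  if (any(fatigue_level < 0 | fatigue_level > 1)) {
    stop("resulting_patient_torque: fatigue_level must lie in [0, 1]",
         call. = FALSE)
  }
  t_fat <- fatigue_level * attenuation_gain * max_active_torque
  mag <- pmax(0, pmin(abs(model_torque), abs(model_torque) - t_fat))
  sign(model_torque) * mag
}

#' One assist-as-needed control step of the combined phase
#'
#' The robot supplies whatever the desired motion requires beyond what the
#' fatigued patient can deliver: the inverse-dynamics torque of the
#' desired state minus the fatigue-attenuated patient torque, per axis.
#'
#' @param desired a [wrist_state()] with accelerations (the desired
#'   motion).
#' @param params,K,B plant parameters.
#' @param patient_torque length-2 numeric, nominal patient torque about
#'   (FE, RUD) (Nm).
#' @param fatigue_level current fatigue estimate in `[0, 1]`.
#' @param max_active_torque patient's measured peak torque (Nm).
#' @param attenuation_gain fatigue mapping gain.
#' @return List with `robot_torque`, `patient_effective` and
#'   `required_torque`, each a length-2 numeric (FE, RUD) in Nm.
#' @export
combined_phase_step <- function(desired, params, K, B,
                                patient_torque = c(0, 0),
                                fatigue_level = 0,
                                max_active_torque = 0,
                                attenuation_gain = 1) {
  td <- inverse_dynamics(desired, params, K, B)
  required <- c(td$T_b, td$T_g)
  eff <- resulting_patient_torque(patient_torque, fatigue_level,
                                  max_active_torque, attenuation_gain)
  list(robot_torque = required - eff,
       patient_effective = eff,
       required_torque = required)
}

#' Run the combined phase on a virtual patient
#'
#' Computes the robot torque command along a desired trajectory via
#' [combined_phase_step()] (patient torque and fatigue sampled from the
#' patient's scripts), then simulates the plant under the total applied
#' torque (robot + effective patient) and reports the tracking error.
#'
#' @param vp a [virtual_patient()].
#' @param desired_fn function `t -> list(beta, gamma, beta_dot, gamma_dot,
#'   beta_ddot, gamma_ddot)` describing the desired motion.
#' @param max_active_torque patient's measured peak torque (Nm).
#' @param config a [session_config()].
#' @return List with the simulated `trajectory`, the desired angles, the
#'   robot torque log and `rms_error_rad` (RMS FE+RUD angle error).
#' @export
run_combined_phase <- function(vp, desired_fn, max_active_torque,
                               config = session_config()) {
  stopifnot(inherits(vp, "virtual_patient"))
  total_torque <- function(t) {
    d <- desired_fn(t)
    st <- wrist_state(d$beta, d$gamma, d$beta_dot, d$gamma_dot,
                      d$beta_ddot, d$gamma_ddot)
    stp <- combined_phase_step(
      st, vp$params, vp$K, vp$B,
      patient_torque = c(vp$effort_script(t), 0),
      fatigue_level = min(1, max(0, vp$fatigue_script(t))),
      max_active_torque = max_active_torque,
      attenuation_gain = config$attenuation_gain)
    stp$robot_torque + stp$patient_effective
  }
  d0 <- desired_fn(0)
  traj <- forward_simulate(
    wrist_state(d0$beta, d0$gamma, d0$beta_dot, d0$gamma_dot),
    total_torque, vp$params, vp$K, vp$B,
    dt = config$dt, duration = config$combined_duration)
  des <- lapply(traj$time_s, desired_fn)
  db <- vapply(des, `[[`, numeric(1), "beta")
  dg <- vapply(des, `[[`, numeric(1), "gamma")
  err <- sqrt(mean((traj$beta_rad - db)^2 + (traj$gamma_rad - dg)^2))
  list(trajectory = traj,
       desired = data.frame(time_s = traj$time_s, beta_rad = db,
                            gamma_rad = dg),
       rms_error_rad = err)
}

#' Motor torque from measured current
#'
#' @param current motor current (A).
#' @param torque_constant motor torque constant (Nm/A), `> 0`.
#' @return Torque (Nm).
#' @export
torque_from_current <- function(current, torque_constant) {
  if (any(!is.finite(current)) || !is.finite(torque_constant) ||
      torque_constant <= 0) {
    stop("torque_from_current: torque_constant must be > 0 and current finite",
         call. = FALSE)
  }
  current * torque_constant
}

#' Healthy-subject wrist range of motion reference
#'
#' Typical healthy ranges per movement (degrees) and the reference RoM
#' used as the denominator of the rehabilitation performance factor.
#'
#' @param reference_rom RPF denominator (degrees); default 90.
#' @return List of class `healthy_rom_table`.
#' @export
healthy_rom_table <- function(reference_rom = 90) {
  if (reference_rom <= 0) {
    stop("healthy_rom_table: reference_rom must be positive", call. = FALSE)
  }
  structure(list(flexion = c(80, 90), extension = c(70, 90),
                 radial = 15, ulnar = c(30, 45),
                 reference_rom = reference_rom),
            class = "healthy_rom_table")
}

#' Rehabilitation performance factor (RPF)
#'
#' Ten-point rating of an achieved range of motion against the maximum a
#' healthy subject reaches: `10 * rom_deg / reference_rom`, truncated
#' (floored) to one decimal and capped at 10. Truncation, not rounding:
#' 62 degrees against 90 gives 6.888..., reported as 6.8.
#'
#' @param rom_deg achieved range of motion (degrees), `>= 0`.
#' @param reference_rom healthy reference RoM (degrees) or a
#'   [healthy_rom_table()]; default 90.
#' @return Rating on `[0, 10]`, one decimal.
#' @examples
#' rpf(45)  # 5.0
#' rpf(62)  # 6.8
#' rpf(72)  # 8.0
#' @export
rpf <- function(rom_deg, reference_rom = 90) {
  if (inherits(reference_rom, "healthy_rom_table")) {
    reference_rom <- reference_rom$reference_rom
  }
  if (any(!is.finite(rom_deg)) || any(rom_deg < 0)) {
    stop("rpf: rom_deg must be finite and >= 0", call. = FALSE)
  }
  # +1e-9 guards one-decimal truncation against binary representation of
  # exactly-representable ratios (e.g. 27/90 must give 3.0, not 2.9)
  pmin(10, floor(100 * rom_deg / reference_rom + 1e-9) / 10)
}

#' One session's outcome record
#'
#' @param subject_id subject label.
#' @param date session date (`Date` or ISO string).
#' @param movement `"FE"` or `"RUD"`.
#' @param phase phase reached, one of [protocol_phases()].
#' @param rom_deg achieved range of motion (degrees).
#' @param rpf rating on the ten-point scale.
#' @param passive_stiffness identified direct stiffness for the exercised
#'   movement (Nm/rad).
#' @param max_active_torque peak active torque (Nm).
#' @param fatigue_trace optional data frame (`window_start_s`, `fatigue`).
#' @param params_snapshot optional [inertial_params()] snapshot.
#' @return A list of class `session_record`.
#' @export
session_record <- function(subject_id, date, movement, phase, rom_deg,
                           rpf, passive_stiffness, max_active_torque,
                           fatigue_trace = NULL, params_snapshot = NULL) {
  movement <- match.arg(movement, c("FE", "RUD"))
  phase <- match.arg(phase, protocol_phases())
  if (rom_deg < 0) stop("session_record: rom_deg must be >= 0", call. = FALSE)
  if (rpf < 0 || rpf > 10) {
    stop("session_record: rpf must lie in [0, 10]", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 date = as.Date(date), movement = movement, phase = phase,
                 rom_deg = rom_deg, rpf = rpf,
                 passive_stiffness = passive_stiffness,
                 max_active_torque = max_active_torque,
                 fatigue_trace = fatigue_trace,
                 params_snapshot = params_snapshot),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("session_record %s %s [%s, %s]: RoM %.1f deg, RPF %.1f, K %.3g Nm/rad, T_max %.3g Nm\n",
              x$subject_id, format(x$date), x$movement, x$phase,
              x$rom_deg, x$rpf, x$passive_stiffness, x$max_active_torque))
  invisible(x)
}

#' Follow-up report over a set of session records
#'
#' Chronological per-subject summary of RoM and RPF progression together
#' with the passive-stiffness and active-torque trends; deterministic
#' given the records. Render as text with `print()` or serialize with
#' [write_report()].
#'
#' @param records list of [session_record()]s (any order; sorted by date
#'   within subject).
#' @return An object of class `session_report`.
#' @export
generate_report <- function(records) {
  if (length(records) < 1) {
    stop("generate_report: need at least one session record", call. = FALSE)
  }
  stopifnot(all(vapply(records, inherits, logical(1), "session_record")))
  ids <- vapply(records, `[[`, character(1), "subject_id")
  subjects <- lapply(split(records, ids), function(rs) {
    rs <- rs[order(vapply(rs, function(r) as.numeric(r$date), numeric(1)))]
    sess <- data.frame(
      date = as.Date(vapply(rs, function(r) format(r$date), character(1))),
      movement = vapply(rs, `[[`, character(1), "movement"),
      phase = vapply(rs, `[[`, character(1), "phase"),
      rom_deg = vapply(rs, `[[`, numeric(1), "rom_deg"),
      rpf = vapply(rs, `[[`, numeric(1), "rpf"),
      stiffness_Nm_per_rad = vapply(rs, `[[`, numeric(1), "passive_stiffness"),
      active_torque_Nm = vapply(rs, `[[`, numeric(1), "max_active_torque")
    )
    n <- nrow(sess)
    list(subject_id = rs[[1]]$subject_id, sessions = sess,
         trend = list(rom_change_deg = sess$rom_deg[n] - sess$rom_deg[1],
                      rpf_change = sess$rpf[n] - sess$rpf[1],
                      stiffness_change = sess$stiffness_Nm_per_rad[n] -
                        sess$stiffness_Nm_per_rad[1],
                      torque_change = sess$active_torque_Nm[n] -
                        sess$active_torque_Nm[1]))
  })
  structure(list(subjects = subjects, n_records = length(records)),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("session_report: %d record(s), %d subject(s)\n",
              x$n_records, length(x$subjects)))
  for (s in x$subjects) {
    n <- nrow(s$sessions)
    cat(sprintf("  %s: %d session(s), %s .. %s\n", s$subject_id, n,
                format(s$sessions$date[1]), format(s$sessions$date[n])))
    cat(sprintf("    RoM %.1f -> %.1f deg (RPF %.1f -> %.1f)\n",
                s$sessions$rom_deg[1], s$sessions$rom_deg[n],
                s$sessions$rpf[1], s$sessions$rpf[n]))
    cat(sprintf("    stiffness %.3g -> %.3g Nm/rad, active torque %.3g -> %.3g Nm\n",
                s$sessions$stiffness_Nm_per_rad[1],
                s$sessions$stiffness_Nm_per_rad[n],
                s$sessions$active_torque_Nm[1],
                s$sessions$active_torque_Nm[n]))
  }
  invisible(x)
}

#' Write a session report as JSON
#'
#' @param report a `session_report` from [generate_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  doc <- lapply(unname(report$subjects), function(s) {
    sess <- s$sessions
    sess$date <- format(sess$date)
    list(subject_id = s$subject_id, sessions = sess, trend = s$trend)
  })
  jsonlite::write_json(list(subjects = doc, n_records = report$n_records),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Run a complete three-phase session on a virtual patient
#'
#' Orchestrates the protocol state machine: passive identification, the
#' resistive capacity test, then -- only if the patient produced readable
#' torque (or the clinician override is set) -- the combined
#' assist-as-needed phase with EMG-based fatigue estimation. An unreadable
#' resistive result routes back to a second passive block, and the session
#' record reports the phase actually reached.
#'
#' @param vp a [virtual_patient()].
#' @param config a [session_config()].
#' @param emg_cfg an [emg_synth_config()] for the session EMG; its
#'   duration should match `config$combined_duration`.
#' @param rb fuzzy rule base for fatigue estimation.
#' @param date session date.
#' @return List with the [session_record()] (`record`) and phase details
#'   (`passive`, `resistive`, `fatigue_trace`).
#' @export
run_session <- function(vp, config = session_config(),
                        emg_cfg = emg_synth_config(
                          duration = config$combined_duration,
                          seed = vp$seed),
                        rb = default_rule_base(),
                        date = Sys.Date()) {
  stopifnot(inherits(vp, "virtual_patient"))
  passive <- run_passive_phase(vp, config)
  resistive <- run_resistive_phase(vp, config)
  phase <- "PATIENT_ACTIVE_ROBOT_RESISTIVE"
  fatigue_trace <- NULL
  if (resistive$readable || config$allow_combined_override) {
    phase <- "BOTH_ACTIVE"
    emg <- synth_emg(emg_cfg, vp$fatigue_script)
    feats <- windowed_features(emg)
    fatigue_trace <- estimate_fatigue_trace(
      feats, rb, baseline_windows = config$baseline_windows)
  } else {
    # unreadable torque: repeat passive exercise, model stays passive-only
    phase <- "PASSIVE_ROBOT_ACTIVE"
  }
  k_main <- if (config$movement == "FE") passive$K$Kbb else passive$K$Kgg
  rec <- session_record(
    subject_id = vp$subject_id, date = date, movement = config$movement,
    phase = phase, rom_deg = resistive$rom_deg,
    rpf = rpf(resistive$rom_deg, config$reference_rom),
    passive_stiffness = k_main,
    max_active_torque = resistive$max_active_torque,
    fatigue_trace = fatigue_trace, params_snapshot = vp$params)
  list(record = rec, passive = passive, resistive = resistive,
       fatigue_trace = fatigue_trace)
}
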