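# Run code with a temporary, restored RNG state so generators are pure
# functions of (config, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Virtual patient: a wrist plant with scripted behaviour
#'
#' Stands in for a study participant: a ground-truth impedance plant
#' (inertial, stiffness and damping parameters) plus deterministic scripts
#' describing what the patient does during active phases -- the torque they
#' produce, the excursion they achieve, and how fatigued they are over
#' session time.
#'
#' @param params an [inertial_params()].
#' @param K a positive-definite [stiffness_tensor()].
#' @param B a positive-semidefinite [damping_tensor()].
#' @param effort_script function `t -> Nm`, patient torque about the
#'   exercised axis; default no effort.
#' @param fatigue_script function `t -> [0,1]`; default 0 (fresh).
#' @param excursion_script function `t -> rad`, achieved angle during the
#'   resistive phase; default rest at neutral.
#' @param seed integer seed from which all of the patient's stochastic
#'   measurements derive.
#' @param subject_id opaque label.
#' @return An object of class `virtual_patient`.
#' @export
virtual_patient <- function(params, K, B = build_damping_tensor(K),
                            effort_script = function(t) 0 * t,
                            fatigue_script = function(t) 0 * t,
                            excursion_script = function(t) 0 * t,
                            seed = 1L, subject_id = "virtual") {
  stopifnot(inherits(params, "inertial_params"),
            inherits(K, "stiffness_tensor"),
            inherits(B, "damping_tensor"))
  if (!is_positive_definite(K)) {
    stop("virtual_patient: stiffness tensor must be positive definite",
         call. = FALSE)
  }
  structure(list(params = params, K = K, B = B,
                 effort_script = effort_script,
                 fatigue_script = fatigue_script,
                 excursion_script = excursion_script,
                 seed = as.integer(seed),
                 subject_id = as.character(subject_id)),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("virtual_patient '%s' (seed %d)\n", x$subject_id, x$seed))
  print(x$K); print(x$B)
  invisible(x)
}

#' Synthetic passive force--displacement trial
#'
#' Emulates the robot slowly sweeping the relaxed wrist through a symmetric
#' ramp about neutral at constant angular speed, recording the torque about
#' the commanded axis and the orthogonal axis at every displacement sample,
#' with optional additive Gaussian measurement noise on the torques.
#'
#' The sweep is checked for quasi-staticity (peak inertial torque below 1%
#' of peak stiffness torque); a violation attaches a warning flag rather
#' than failing, mirroring how a too-fast robot ramp would corrupt a slope
#' fit.
#'
#' @param vp a [virtual_patient()].
#' @param movement `"FE"` or `"RUD"`.
#' @param amplitude ramp amplitude (rad); sweep covers `[-amplitude,
#'   amplitude]`.
#' @param speed constant angular speed (rad/s).
#' @param noise_sd torque measurement noise SD (Nm); 0 for noiseless.
#' @param n_samples number of displacement samples.
#' @param seed RNG seed for the noise; defaults to the patient's seed.
#' @return A [passive_trial()]; attribute `quasi_static_ok` flags the
#'   speed check.
#' @export
synth_passive_trial <- function(vp, movement = c("FE", "RUD"),
                                amplitude = 0.3, speed = 0.1,
                                noise_sd = 0, n_samples = 201,
                                seed = vp$seed) {
  stopifnot(inherits(vp, "virtual_patient"))
  movement <- match.arg(movement)
  disp <- seq(-amplitude, amplitude, length.out = n_samples)
  if (movement == "FE") {
    tt <- .impedance_terms(beta = disp, gamma = 0, beta_dot = speed,
                           gamma_dot = 0, beta_ddot = 0, gamma_ddot = 0,
                           vp$params, vp$K, vp$B)
    main <- tt$T_b; cross <- tt$T_g
    stiff <- tt$T_stiff_b
    m_axis <- .m_beta(0, vp$params)
  } else {
    tt <- .impedance_terms(beta = 0, gamma = disp, beta_dot = 0,
                           gamma_dot = speed, beta_ddot = 0, gamma_ddot = 0,
                           vp$params, vp$K, vp$B)
    main <- tt$T_g; cross <- tt$T_b
    stiff <- tt$T_stiff_g
    m_axis <- vp$params$Ix
  }
  # quasi-static check: the inertial torque needed to reverse the sweep
  # (characteristic acceleration speed^2/amplitude) must stay below 1% of
  # the peak stiffness torque
  ok <- m_axis * speed^2 / amplitude < 0.01 * max(abs(stiff))
  if (!ok) {
    warning("synth_passive_trial: ramp not quasi-static (inertial torque > 1% of stiffness torque)",
            call. = FALSE)
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * n_samples, sd = noise_sd))
    main <- main + noise[1:n_samples]
    cross <- cross + noise[(n_samples + 1):(2 * n_samples)]
  }
  out <- passive_trial(movement, disp, main, cross)
  attr(out, "quasi_static_ok") <- ok
  out
}

#' Configuration of the synthetic fatiguing-EMG generator
#'
#' Encodes the standard fatigue phenomenology the classifier assumes:
#' as fatigue grows, the EMG power spectrum compresses toward low
#' frequencies (centre frequency `base_mnf + mnf_drift * fatigue`) and the
#' amplitude grows (`amp_gain ^ fatigue`).
#'
#' @param fs sampling rate (Hz); default 1000.
#' @param duration record length (s).
#' @param base_mnf fresh-muscle spectral centre (Hz); default 95.
#' @param mnf_drift centre-frequency shift per unit fatigue (Hz, negative);
#'   default -40.
#' @param amp_gain amplitude multiplier at full fatigue (>= 1);
#'   default 1.5.
#' @param noise_floor white-noise floor relative to signal SD; default
#'   0.05.
#' @param bandwidth spectral half-power width of the shaping resonator
#'   (Hz); default 20.
#' @param seed integer RNG seed.
#' @return An object of class `emg_synth_config`.
#' @export
emg_synth_config <- function(fs = 1000, duration = 30, base_mnf = 95,
                             mnf_drift = -40, amp_gain = 1.5,
                             noise_floor = 0.05, bandwidth = 20,
                             seed = 1L) {
  if (duration <= 0) {
    stop("emg_synth_config: duration must be > 0", call. = FALSE)
  }
  if (fs <= 2 * (base_mnf + 3 * bandwidth)) {
    stop("emg_synth_config: fs must exceed twice the top of the signal band",
         call. = FALSE)
  }
  if (amp_gain < 1) {
    stop("emg_synth_config: amp_gain must be >= 1", call. = FALSE)
  }
  structure(list(fs = fs, duration = duration, base_mnf = base_mnf,
                 mnf_drift = mnf_drift, amp_gain = amp_gain,
                 noise_floor = noise_floor, bandwidth = bandwidth,
                 seed = as.integer(seed)),
            class = "emg_synth_config")
}

#' Synthetic fatiguing surface EMG
#'
#' Seeded white noise shaped by a time-varying two-pole resonator whose
#' centre frequency tracks `base_mnf + mnf_drift * fatigue(t)`, then scaled
#' by `amp_gain ^ fatigue(t)` and mixed with a white noise floor. The
#' result reproduces the spectral compression and amplitude growth of
#' fatiguing muscle without modelling motor units -- the downstream
#' classifier only consumes spectra, so spectral realism suffices.
#'
#' @param cfg an [emg_synth_config()].
#' @param fatigue_trajectory function `t -> [0, 1]`; default a linear ramp
#'   0 to 1 over the record.
#' @return An [emg_record()].
#' @export
synth_emg <- function(cfg,
                      fatigue_trajectory = function(t) t / cfg$duration) {
  stopifnot(inherits(cfg, "emg_synth_config"))
  n <- round(cfg$fs * cfg$duration)
  t <- (seq_len(n) - 1) / cfg$fs
  fat <- pmin(1, pmax(0, fatigue_trajectory(t)))
  fc <- cfg$base_mnf + cfg$mnf_drift * fat
  r <- exp(-pi * cfg$bandwidth / cfg$fs)
  theta <- 2 * pi * fc / cfg$fs
  a1 <- 2 * r * cos(theta)
  a2 <- -r * r
  noise <- with_seed(cfg$seed, stats::rnorm(2 * n))
  x <- noise[1:n]
  y <- numeric(n)
  y[1] <- x[1]
  if (n >= 2) y[2] <- a1[2] * y[1] + x[2]
  for (i in 3:n) y[i] <- a1[i] * y[i - 1] + a2 * y[i - 2] + x[i]
  y <- y / stats::sd(y)
  sig <- y * cfg$amp_gain^fat
  sig <- sig + cfg$noise_floor * noise[(n + 1):(2 * n)]
  emg_record(sig, cfg$fs, "synthetic")
}

#' Generate a full synthetic session bundle on disk
#'
#' Produces, deterministically from the patient's seed, every file a
#' recorded session would supply: passive FE and RUD trials, the resistive
#' -phase log, the session EMG, and the patient parameter file -- laid out
#' as the command-line consumers expect.
#'
#' @param vp a [virtual_patient()].
#' @param emg_cfg an [emg_synth_config()]; its `duration` must equal the
#'   protocol's combined-phase duration.
#' @param config a [session_config()].
#' @param out_dir directory to create/populate.
#' @return Invisibly, a named list of the file paths written.
#' @export
synth_session <- function(vp, emg_cfg, config = session_config(),
                          out_dir) {
  stopifnot(inherits(vp, "virtual_patient"),
            inherits(emg_cfg, "emg_synth_config"))
  if (abs(emg_cfg$duration - config$combined_duration) > 1e-9) {
    stop("synth_session: EMG duration must match the combined-phase duration",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fe <- synth_passive_trial(vp, "FE", config$passive_amplitude,
                            config$passive_speed, config$passive_noise_sd,
                            seed = vp$seed + 11L)
  rud <- synth_passive_trial(vp, "RUD", config$passive_amplitude,
                             config$passive_speed, config$passive_noise_sd,
                             seed = vp$seed + 12L)
  times <- seq(0, config$resistive_duration, by = config$dt)
  resist <- data.frame(time_s = times,
                       angle_rad = vp$excursion_script(times),
                       torque_Nm = vp$effort_script(times))
  emg <- synth_emg(emg_cfg, vp$fatigue_script)

  paths <- list(
    fe_trial = file.path(out_dir, "passive_fe.csv"),
    rud_trial = file.path(out_dir, "passive_rud.csv"),
    resistive = file.path(out_dir, "resistive.csv"),
    emg = file.path(out_dir, "emg.csv"),
    patient = file.path(out_dir, "patient.yaml")
  )
  write_passive_trial_csv(fe, paths$fe_trial)
  write_passive_trial_csv(rud, paths$rud_trial)
  utils::write.csv(resist, paths$resistive, row.names = FALSE)
  write_emg_csv(emg, paths$emg)
  write_subject_params_yaml(vp$params, vp$K, vp$B, paths$patient,
                            subject_id = vp$subject_id)
  invisible(paths)
}
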