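#' Subject anthropometry record
#'
#' Minimal measurements the therapist records for a new subject, from which
#' the inertial model parameters are derived.
#'
#' @param hand_length hand length, wrist crease to tip of middle finger (m).
#' @param forearm_length forearm length (m).
#' @param hand_mass hand mass (kg).
#' @param subject_id opaque subject label.
#' @return An object of class `anthropometry`.
#' @export
anthropometry <- function(hand_length, forearm_length, hand_mass,
                          subject_id = "anonymous") {
  if (!all(is.finite(c(hand_length, forearm_length, hand_mass))) ||
      hand_length <= 0 || forearm_length <= 0 || hand_mass <= 0) {
    stop("anthropometry: lengths and mass must be positive finite numbers",
         call. = FALSE)
  }
  structure(list(hand_length = hand_length, forearm_length = forearm_length,
                 hand_mass = hand_mass, subject_id = as.character(subject_id)),
            class = "anthropometry")
}

#' Default anthropometric coefficients for the ellipsoidal hand model
#'
#' The hand is modelled as a solid homogeneous ellipsoid whose semi-axes are
#' fixed fractions of hand length: `c_length` along the longitudinal (y)
#' axis, `c_width` along the medio-lateral (z, FE) axis and `c_thickness`
#' along the dorso-palmar (x, RUD) axis. `c_com` places the hand centre of
#' mass at that fraction of hand length from the wrist axes (used for
#' `rCD`). All four are overridable in [inertial_from_anthropometry()].
#'
#' @return Named list of the four coefficients (dimensionless).
#' @export
anthro_coefficients <- function() {
  list(c_com = 0.506, c_length = 0.5, c_width = 0.22, c_thickness = 0.12)
}

#' Inertial parameters from anthropometry
#'
#' Derives the hand mass, centre-of-mass offset and moments of inertia from
#' segment lengths via the ellipsoidal hand model (see
#' [anthro_coefficients()]). A solid ellipsoid of mass `m` and semi-axes
#' `(a, b, c)` has moments `m/5 * (b^2 + c^2)` about the `a` axis, etc.
#' The axis offset defaults to 4 mm for every subject and the wrist-link
#' inertia is neglected (`Iw = 0`), both settable downstream.
#'
#' @param a an [anthropometry()] record.
#' @param coeffs coefficient list as returned by [anthro_coefficients()];
#'   individual entries may be overridden.
#' @param rAC axis offset (m); default 0.004.
#' @param g gravitational acceleration (m/s^2).
#' @return An [inertial_params()] object.
#' @examples
#' inertial_from_anthropometry(anthropometry(0.19, 0.26, 0.45))
#' @export
inertial_from_anthropometry <- function(a, coeffs = anthro_coefficients(),
                                        rAC = 0.004, g = 9.81) {
  stopifnot(inherits(a, "anthropometry"))
  co <- utils::modifyList(anthro_coefficients(), as.list(coeffs))
  hl <- a$hand_length
  m <- a$hand_mass
  # ellipsoid semi-axes: longitudinal (y), medio-lateral (z), dorso-palmar (x)
  s_l <- co$c_length * hl
  s_w <- co$c_width * hl
  s_t <- co$c_thickness * hl
  inertial_params(
    m = m,
    Ix = m / 5 * (s_l^2 + s_w^2),  # about the RUD (dorso-palmar) axis
    Iy = m / 5 * (s_t^2 + s_w^2),  # about the longitudinal axis
    Iz = m / 5 * (s_l^2 + s_t^2),  # about the FE (medio-lateral) axis
    rCD = co$c_com * hl,
    Iw = 0, rAC = rAC, g = g
  )
}

#' Passive force--displacement trial
#'
#' One slow robot-imposed rotation of the relaxed wrist away from neutral,
#' with the torque about the commanded axis (and optionally about the
#' orthogonal axis) recorded at each displacement sample.
#'
#' @param direction `"FE"` or `"RUD"` -- the commanded axis.
#' @param displacements displacement samples (rad).
#' @param torques_main torque about the commanded axis (Nm).
#' @param torques_cross optional torque about the orthogonal axis (Nm).
#' @return An object of class `passive_trial`.
#' @export
passive_trial <- function(direction, displacements, torques_main,
                          torques_cross = NULL) {
  direction <- match.arg(direction, c("FE", "RUD"))
  n <- length(displacements)
  if (n < 3) {
    stop("passive_trial: need at least 3 samples", call. = FALSE)
  }
  if (length(torques_main) != n ||
      (!is.null(torques_cross) && length(torques_cross) != n)) {
    stop("passive_trial: displacement and torque lengths differ",
         call. = FALSE)
  }
  if (!all(is.finite(c(displacements, torques_main, torques_cross)))) {
    stop("passive_trial: non-finite samples", call. = FALSE)
  }
  if (diff(range(displacements)) <= 0) {
    stop("passive_trial: displacements span a zero range", call. = FALSE)
  }
  structure(list(direction = direction,
                 displacements = as.numeric(displacements),
                 torques_main = as.numeric(torques_main),
                 torques_cross = if (is.null(torques_cross)) NULL
                                 else as.numeric(torques_cross)),
            class = "passive_trial")
}

#' @export
print.passive_trial <- function(x, ...) {
  cat(sprintf("passive_trial (%s): %d samples, displacement %.3g..%.3g rad%s\n",
              x$direction, length(x$displacements),
              min(x$displacements), max(x$displacements),
              if (is.null(x$torques_cross)) "" else ", cross-axis recorded"))
  invisible(x)
}

# OLS slope of y on x with intercept; the intercept absorbs sensor bias and
# the constant damping offset of a constant-velocity ramp.
.ols_slope <- function(x, y, what) {
  if (length(x) < 3) {
    stop(sprintf("estimate_stiffness: fewer than 3 samples for %s", what),
         call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop(sprintf("estimate_stiffness: zero displacement variance for %s (singular fit)",
                 what), call. = FALSE)
  }
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Passive stiffness tensor from force--displacement trials
#'
#' The stiffness in each direction is the least-squares slope of the linear
#' approximation of the torque--displacement relationship in that
#' direction: `Kbb` from the FE trial, `Kgg` from the RUD trial. When the
#' orthogonal-axis torque was recorded, the cross term `Kbg` is the mean of
#' the two cross slopes (RUD torque vs FE displacement and vice versa);
#' otherwise it is 0. The result is symmetric by construction.
#'
#' @param fe_trial a [passive_trial()] with `direction = "FE"`.
#' @param rud_trial a [passive_trial()] with `direction = "RUD"`.
#' @return A [stiffness_tensor()] (Nm/rad).
#' @export
estimate_stiffness <- function(fe_trial, rud_trial) {
  stopifnot(inherits(fe_trial, "passive_trial"),
            inherits(rud_trial, "passive_trial"))
  if (fe_trial$direction != "FE" || rud_trial$direction != "RUD") {
    stop("estimate_stiffness: trials must be (FE, RUD) in that order",
         call. = FALSE)
  }
  Kbb <- .ols_slope(fe_trial$displacements, fe_trial$torques_main, "FE main")
  Kgg <- .ols_slope(rud_trial$displacements, rud_trial$torques_main,
                    "RUD main")
  cross <- c(
    if (!is.null(fe_trial$torques_cross))
      .ols_slope(fe_trial$displacements, fe_trial$torques_cross, "FE cross"),
    if (!is.null(rud_trial$torques_cross))
      .ols_slope(rud_trial$displacements, rud_trial$torques_cross, "RUD cross")
  )
  Kbg <- if (length(cross) > 0) mean(cross) else 0
  stiffness_tensor(Kbb = Kbb, Kbg = Kbg, Kgg = Kgg)
}

#' Damping tensor proportional to the stiffness tensor
#'
#' Wrist passive viscosity is identified only in pure FE, so the full
#' damping tensor is taken proportional to the stiffness tensor with the
#' proportionality constant chosen to give the prescribed pure-FE damping:
#' `B = c K` with `c = pure_fe_damping / Kbb`, hence `Bbb` equals
#' `pure_fe_damping` exactly.
#'
#' @param K a [stiffness_tensor()] with `Kbb > 0`.
#' @param pure_fe_damping damping in pure FE (Nms/rad); default 0.03.
#' @return A [damping_tensor()].
#' @examples
#' build_damping_tensor(stiffness_tensor(3, 0.5, 2))
#' @export
build_damping_tensor <- function(K, pure_fe_damping = 0.03) {
  stopifnot(inherits(K, "stiffness_tensor"))
  if (K$Kbb <= 0) {
    stop("build_damping_tensor: Kbb must be > 0", call. = FALSE)
  }
  cc <- pure_fe_damping / K$Kbb
  damping_tensor(Bbb = pure_fe_damping, Bbg = cc * K$Kbg, Bgg = cc * K$Kgg)
}
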