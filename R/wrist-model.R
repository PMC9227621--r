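#' Wrist kinematic state
#'
#' Bundles the angular pose, velocity and (optionally) acceleration of the
#' two fundamental wrist degrees of freedom: flexion--extension (FE, angle
#' `beta`, about the forearm-fixed Z axis) and radial--ulnar deviation (RUD,
#' angle `gamma`, about the rotated x axis). Angles are radians, neutral
#' posture is `beta = gamma = 0`, flexion and radial deviation positive.
#'
#' Accelerations may be omitted (`NULL`): forward simulation fills them in,
#' while [inverse_dynamics()] requires them.
#'
#' @param beta FE angle (rad).
#' @param gamma RUD angle (rad).
#' @param beta_dot,gamma_dot angular velocities (rad/s).
#' @param beta_ddot,gamma_ddot angular accelerations (rad/s^2), or `NULL`.
#' @return An object of class `wrist_state`.
#' @examples
#' wrist_state(0.2, -0.1, beta_dot = 0.5, gamma_dot = 0)
#' @export
wrist_state <- function(beta, gamma, beta_dot = 0, gamma_dot = 0,
                        beta_ddot = NULL, gamma_ddot = NULL) {
  vals <- c(beta, gamma, beta_dot, gamma_dot, beta_ddot, gamma_ddot)
  if (!all(is.finite(vals))) {
    stop("wrist_state: all components must be finite numbers", call. = FALSE)
  }
  if (abs(beta) >= pi || abs(gamma) >= pi) {
    stop("wrist_state: |beta| and |gamma| must be < pi rad", call. = FALSE)
  }
  structure(
    list(beta = beta, gamma = gamma,
         beta_dot = beta_dot, gamma_dot = gamma_dot,
         beta_ddot = beta_ddot, gamma_ddot = gamma_ddot),
    class = "wrist_state"
  )
}

#' @export
print.wrist_state <- function(x, ...) {
  cat(sprintf("wrist_state: beta=%.4g rad, gamma=%.4g rad\n", x$beta, x$gamma))
  cat(sprintf("  rates: beta_dot=%.4g, gamma_dot=%.4g rad/s\n",
              x$beta_dot, x$gamma_dot))
  if (!is.null(x$beta_ddot)) {
    cat(sprintf("  accel: beta_ddot=%.4g, gamma_ddot=%.4g rad/s^2\n",
                x$beta_ddot, x$gamma_ddot))
  }
  invisible(x)
}

#' Inertial and geometric parameters of the hand--wrist system
#'
#' @param m hand mass (kg).
#' @param Ix,Iy,Iz hand moments of inertia about the hand-fixed x, y, z axes
#'   at the hand centre of mass (kg m^2).
#' @param rCD distance from the hand centre of mass to the distal (RUD) axis
#'   (m).
#' @param Iw inertia of the wrist link about Z (kg m^2). Small compared with
#'   `Iz`; default 0.
#' @param rAC perpendicular offset between the non-intersecting FE and RUD
#'   axes (m); default 0.004 (4 mm), the value assigned to every subject.
#' @param g gravitational acceleration (m/s^2).
#' @return An object of class `inertial_params`.
#' @export
inertial_params <- function(m, Ix, Iy, Iz, rCD, Iw = 0, rAC = 0.004,
                            g = 9.81) {
  if (!all(is.finite(c(m, Ix, Iy, Iz, rCD, Iw, rAC, g)))) {
    stop("inertial_params: all parameters must be finite", call. = FALSE)
  }
  if (m <= 0 || Ix <= 0 || Iy <= 0 || Iz <= 0) {
    stop("inertial_params: m, Ix, Iy, Iz must be positive", call. = FALSE)
  }
  if (Iw < 0 || rAC < 0 || rCD < 0) {
    stop("inertial_params: Iw, rAC, rCD must be non-negative", call. = FALSE)
  }
  structure(list(m = m, Ix = Ix, Iy = Iy, Iz = Iz, rCD = rCD,
                 Iw = Iw, rAC = rAC, g = g),
            class = "inertial_params")
}

#' @export
print.inertial_params <- function(x, ...) {
  cat("inertial_params:\n")
  cat(sprintf("  m=%.4g kg, rCD=%.4g m, rAC=%.4g m, Iw=%.3g kg.m^2\n",
              x$m, x$rCD, x$rAC, x$Iw))
  cat(sprintf("  Ix=%.4g, Iy=%.4g, Iz=%.4g kg.m^2, g=%.3f m/s^2\n",
              x$Ix, x$Iy, x$Iz, x$g))
  invisible(x)
}

#' Symmetric 2x2 wrist stiffness tensor
#'
#' Only the three independent elements are stored, so the tensor is
#' symmetric by construction. Units Nm/rad. `Kbg` couples the two degrees
#' of freedom: a pure FE deflection produces an RUD torque `Kbg * beta`.
#'
#' @param Kbb,Kbg,Kgg tensor elements (Nm/rad).
#' @return An object of class `stiffness_tensor`.
#' @export
stiffness_tensor <- function(Kbb, Kbg = 0, Kgg = Kbb) {
  if (!all(is.finite(c(Kbb, Kbg, Kgg)))) {
    stop("stiffness_tensor: elements must be finite", call. = FALSE)
  }
  structure(list(Kbb = Kbb, Kbg = Kbg, Kgg = Kgg),
            class = "stiffness_tensor")
}

#' Symmetric 2x2 wrist damping tensor
#'
#' @param Bbb,Bbg,Bgg tensor elements (Nms/rad).
#' @return An object of class `damping_tensor`.
#' @seealso [build_damping_tensor()] for the proportional construction from
#'   a stiffness tensor.
#' @export
damping_tensor <- function(Bbb, Bbg = 0, Bgg = Bbb) {
  if (!all(is.finite(c(Bbb, Bbg, Bgg)))) {
    stop("damping_tensor: elements must be finite", call. = FALSE)
  }
  structure(list(Bbb = Bbb, Bbg = Bbg, Bgg = Bgg),
            class = "damping_tensor")
}

#' @export
print.stiffness_tensor <- function(x, ...) {
  cat(sprintf("stiffness_tensor (Nm/rad): Kbb=%.4g Kbg=%.4g Kgg=%.4g\n",
              x$Kbb, x$Kbg, x$Kgg))
  invisible(x)
}

#' @export
print.damping_tensor <- function(x, ...) {
  cat(sprintf("damping_tensor (Nms/rad): Bbb=%.4g Bbg=%.4g Bgg=%.4g\n",
              x$Bbb, x$Bbg, x$Bgg))
  invisible(x)
}

#' @export
as.matrix.stiffness_tensor <- function(x, ...) {
  matrix(c(x$Kbb, x$Kbg, x$Kbg, x$Kgg), 2, 2,
         dimnames = list(c("beta", "gamma"), c("beta", "gamma")))
}

#' @export
as.matrix.damping_tensor <- function(x, ...) {
  matrix(c(x$Bbb, x$Bbg, x$Bbg, x$Bgg), 2, 2,
         dimnames = list(c("beta", "gamma"), c("beta", "gamma")))
}

# TRUE iff the symmetric 2x2 tensor is positive definite.
is_positive_definite <- function(x) {
  a <- x[[1]]; b <- x[[2]]; c <- x[[3]]
  a > 0 && c > 0 && a * c - b * b > 0
}

# Configuration-dependent FE inertia coefficient M_beta(gamma).
.m_beta <- function(gamma, p) {
  sg <- sin(gamma); cg <- cos(gamma)
  p$Iw + p$Iy * sg^2 + p$Iz * cg^2 + p$m * p$rAC * (p$rAC + 2 * p$rCD * cg)
}

# Vectorized evaluation of every torque term of the universal-joint model.
# All angle/rate arguments may be vectors of common length.
.impedance_terms <- function(beta, gamma, beta_dot, gamma_dot,
                             beta_ddot, gamma_ddot, p, K, B) {
  sg <- sin(gamma); cg <- cos(gamma)
  m_b <- p$Iw + p$Iy * sg^2 + p$Iz * cg^2 +
    p$m * p$rAC * (p$rAC + 2 * p$rCD * cg)
  # velocity-product (interaction) inertial parts
  inter_b <- beta_dot * gamma_dot *
    (2 * (p$Iy - p$Iz) * sg * cg - 2 * p$m * p$rAC * p$rCD * sg)
  inter_g <- -beta_dot^2 * ((p$Iy - p$Iz) * sg * cg - p$m * p$rAC * p$rCD * sg)
  T_inert_b <- beta_ddot * m_b + inter_b
  T_inert_g <- gamma_ddot * p$Ix + inter_g
  T_damp_b <- B$Bbb * beta_dot + B$Bbg * gamma_dot
  T_damp_g <- B$Bgg * gamma_dot + B$Bbg * beta_dot
  T_stiff_b <- K$Kbb * beta + K$Kbg * gamma
  T_stiff_g <- K$Kgg * gamma + K$Kbg * beta
  T_grav_g <- -p$m * p$g * p$rCD * cg
  list(
    T_inert_b = T_inert_b, T_damp_b = T_damp_b, T_stiff_b = T_stiff_b,
    T_inert_g = T_inert_g, T_damp_g = T_damp_g, T_stiff_g = T_stiff_g,
    T_grav_g = T_grav_g,
    T_b = T_inert_b + T_damp_b + T_stiff_b,
    T_g = T_inert_g + T_damp_g + T_stiff_g + T_grav_g,
    interaction_b = inter_b, interaction_g = inter_g,
    m_beta = m_b
  )
}

#' Inverse dynamics of the 2-DOF wrist impedance model
#'
#' Evaluates the torque about each wrist axis required to produce the given
#' motion, split into inertial, damping, stiffness and (for RUD) gravity
#' components. The wrist is modelled as a universal joint with
#' non-intersecting axes offset by `rAC`; the FE inertia coefficient depends
#' on the RUD angle, and velocity-product "interaction" torques couple the
#' two degrees of freedom.
#'
#' @param state a [wrist_state()] carrying finite accelerations.
#' @param params an [inertial_params()].
#' @param K a [stiffness_tensor()].
#' @param B a [damping_tensor()].
#' @return An object of class `torque_breakdown`: a list with per-axis
#'   component torques (`T_inert_b`, `T_damp_b`, `T_stiff_b`, `T_inert_g`,
#'   `T_damp_g`, `T_stiff_g`, `T_grav_g`), totals (`T_b`, `T_g`) and the
#'   velocity-product interaction parts (`interaction_b`, `interaction_g`),
#'   all in Nm. The totals equal the sums of their components exactly.
#' @examples
#' p <- inertial_params(m = 0.5, Ix = 1e-3, Iy = 1.2e-3, Iz = 8e-4,
#'                      rCD = 0.05)
#' s <- wrist_state(0.2, 0, beta_ddot = 0, gamma_ddot = 0)
#' inverse_dynamics(s, p, stiffness_tensor(3, 0.5, 2), damping_tensor(0.03))
#' @export
inverse_dynamics <- function(state, params, K, B) {
  stopifnot(inherits(state, "wrist_state"),
            inherits(params, "inertial_params"),
            inherits(K, "stiffness_tensor"),
            inherits(B, "damping_tensor"))
  if (is.null(state$beta_ddot) || is.null(state$gamma_ddot)) {
    stop("inverse_dynamics: state must carry accelerations", call. = FALSE)
  }
  tt <- .impedance_terms(state$beta, state$gamma,
                         state$beta_dot, state$gamma_dot,
                         state$beta_ddot, state$gamma_ddot,
                         params, K, B)
  tt$m_beta <- NULL
  structure(tt, class = "torque_breakdown")
}

#' @export
print.torque_breakdown <- function(x, ...) {
  cat(sprintf("torque_breakdown (Nm): T_b=%.5g  T_g=%.5g\n", x$T_b, x$T_g))
  cat(sprintf("  FE : inert=%.4g damp=%.4g stiff=%.4g (interaction %.4g)\n",
              x$T_inert_b, x$T_damp_b, x$T_stiff_b, x$interaction_b))
  cat(sprintf("  RUD: inert=%.4g damp=%.4g stiff=%.4g grav=%.4g (interaction %.4g)\n",
              x$T_inert_g, x$T_damp_g, x$T_stiff_g, x$T_grav_g,
              x$interaction_g))
  invisible(x)
}

#' Inverse dynamics along a whole trajectory
#'
#' Vectorized convenience wrapper: applies the impedance model at every
#' sample of a trajectory, using the stored accelerations.
#'
#' @param traj a `wrist_trajectory` (see [forward_simulate()]) or a
#'   data frame with columns `beta_rad`, `gamma_rad`, `beta_dot`,
#'   `gamma_dot`, `beta_ddot`, `gamma_ddot`.
#' @inheritParams inverse_dynamics
#' @return A data frame with one row per sample and the same columns as a
#'   `torque_breakdown`.
#' @export
inverse_dynamics_trajectory <- function(traj, params, K, B) {
  df <- as.data.frame(traj)
  need <- c("beta_rad", "gamma_rad", "beta_dot", "gamma_dot",
            "beta_ddot", "gamma_ddot")
  if (!all(need %in% names(df))) {
    stop("inverse_dynamics_trajectory: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  tt <- .impedance_terms(df$beta_rad, df$gamma_rad, df$beta_dot, df$gamma_dot,
                         df$beta_ddot, df$gamma_ddot, params, K, B)
  tt$m_beta <- NULL
  out <- as.data.frame(tt)
  if ("time_s" %in% names(df)) out <- cbind(time_s = df$time_s, out)
  out
}

#' Forward simulation of wrist motion under applied torques
#'
#' Integrates the equations of motion obtained by solving the impedance
#' model for the angular accelerations. The FE acceleration coefficient
#' `M_beta(gamma)` is configuration dependent; the RUD coefficient is the
#' constant `Ix`, so the system is explicitly solvable at every state.
#'
#' @param initial a [wrist_state()] (accelerations ignored).
#' @param torque_fn `NULL` for unforced motion, or a function `f(t)`
#'   returning the applied torque pair `c(T_beta, T_gamma)` in Nm.
#' @param params,K,B plant parameters as for [inverse_dynamics()].
#' @param dt output/integration step (s); default 1 ms.
#' @param duration total simulated time (s).
#' @param method `"rk4"` (fixed-step 4th order, default) or `"lsoda"`
#'   (adaptive, for high-accuracy reference runs).
#' @return An object of classes `wrist_trajectory` and `data.frame` with
#'   columns `time_s`, `beta_rad`, `gamma_rad`, `beta_dot`, `gamma_dot`,
#'   `beta_ddot`, `gamma_ddot`, `T_beta_Nm`, `T_gamma_Nm`. Accelerations
#'   are the instantaneous values implied by the plant at each sample, so
#'   inverse dynamics along the trajectory reproduces the applied torques.
#' @examples
#' p <- inertial_params(m = 0.5, Ix = 1e-3, Iy = 1.2e-3, Iz = 8e-4,
#'                      rCD = 0, rAC = 0)
#' tr <- forward_simulate(wrist_state(0.1, 0), NULL, p,
#'                        stiffness_tensor(3, 0, 30), damping_tensor(0.03),
#'                        dt = 1e-3, duration = 0.5)
#' head(tr)
#' @export
forward_simulate <- function(initial, torque_fn, params, K, B,
                             dt = 1e-3, duration,
                             method = c("rk4", "lsoda")) {
  stopifnot(inherits(initial, "wrist_state"),
            inherits(params, "inertial_params"),
            inherits(K, "stiffness_tensor"),
            inherits(B, "damping_tensor"))
  method <- match.arg(method)
  if (dt <= 0) stop("forward_simulate: dt must be > 0", call. = FALSE)
  if (duration < dt) {
    stop("forward_simulate: duration must be >= dt", call. = FALSE)
  }
  if (is.null(torque_fn)) torque_fn <- function(t) c(0, 0)

  accel <- function(t, y) {
    if (any(!is.finite(y))) {
      stop(sprintf("forward_simulate: state diverged (non-finite) at t=%.6g s",
                   t), call. = FALSE)
    }
    beta <- y[1]; gamma <- y[2]; bd <- y[3]; gd <- y[4]
    tau <- torque_fn(t)
    sg <- sin(gamma); cg <- cos(gamma)
    m_b <- params$Iw + params$Iy * sg^2 + params$Iz * cg^2 +
      params$m * params$rAC * (params$rAC + 2 * params$rCD * cg)
    if (m_b <= 0) {
      stop(sprintf(
        "forward_simulate: degenerate inertia M_beta(gamma)=%.3g <= 0 at t=%.6g s",
        m_b, t), call. = FALSE)
    }
    inter_b <- bd * gd *
      (2 * (params$Iy - params$Iz) * sg * cg -
         2 * params$m * params$rAC * params$rCD * sg)
    inter_g <- -bd^2 * ((params$Iy - params$Iz) * sg * cg -
                          params$m * params$rAC * params$rCD * sg)
    bdd <- (tau[1] - inter_b - (B$Bbb * bd + B$Bbg * gd) -
              (K$Kbb * beta + K$Kbg * gamma)) / m_b
    gdd <- (tau[2] - inter_g - (B$Bgg * gd + B$Bbg * bd) -
              (K$Kgg * gamma + K$Kbg * beta) +
              params$m * params$g * params$rCD * cg) / params$Ix
    c(bdd, gdd)
  }
  deriv <- function(t, y, parms) {
    a <- accel(t, y)
    list(c(y[3], y[4], a[1], a[2]))
  }

  times <- seq(0, duration, by = dt)
  y0 <- c(initial$beta, initial$gamma, initial$beta_dot, initial$gamma_dot)
  sol <- if (method == "rk4") {
    deSolve::ode(y0, times, deriv, NULL, method = "rk4")
  } else {
    deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                 rtol = 1e-10, atol = 1e-12)
  }
  sol <- unclass(sol)
  bad <- which(!is.finite(rowSums(sol[, 2:5, drop = FALSE])))
  if (length(bad) > 0) {
    stop(sprintf("forward_simulate: state diverged (non-finite) at t=%.6g s",
                 sol[bad[1], 1]), call. = FALSE)
  }

  tau <- vapply(times, torque_fn, numeric(2))
  acc <- vapply(seq_along(times),
                function(i) accel(times[i], sol[i, 2:5]),
                numeric(2))
  out <- data.frame(
    time_s = times,
    beta_rad = sol[, 2], gamma_rad = sol[, 3],
    beta_dot = sol[, 4], gamma_dot = sol[, 5],
    beta_ddot = acc[1, ], gamma_ddot = acc[2, ],
    T_beta_Nm = tau[1, ], T_gamma_Nm = tau[2, ]
  )
  class(out) <- c("wrist_trajectory", "data.frame")
  out
}

#' Total mechanical energy along a trajectory
#'
#' Kinetic plus elastic plus gravitational potential energy of the wrist
#' plant. For unforced, undamped motion this quantity is a constant of the
#' motion, which makes it a sensitive check on the integrator.
#'
#' @param traj a `wrist_trajectory` or compatible data frame.
#' @param params an [inertial_params()].
#' @param K a [stiffness_tensor()].
#' @return Numeric vector of energies (J), one per sample.
#' @export
wrist_energy <- function(traj, params, K) {
  df <- as.data.frame(traj)
  m_b <- .m_beta(df$gamma_rad, params)
  0.5 * m_b * df$beta_dot^2 + 0.5 * params$Ix * df$gamma_dot^2 +
    0.5 * (K$Kbb * df$beta_rad^2 + 2 * K$Kbg * df$beta_rad * df$gamma_rad +
             K$Kgg * df$gamma_rad^2) -
    params$m * params$g * params$rCD * sin(df$gamma_rad)
}

#' Small-angle linearization of the wrist impedance model
#'
#' Expands the model about the neutral posture (`sin(gamma) -> gamma`,
#' `cos(gamma) -> 1`) and drops the velocity-product terms, yielding a
#' constant-coefficient second-order model: mass matrix
#' `diag(Iw + Iz + m*rAC*(rAC + 2*rCD), Ix)`, the damping and stiffness
#' tensors unchanged, and a constant gravity bias `(0, -m*g*rCD)`.
#' The approximation is good for moderately sized rotations because
#' stiffness, not inertia, dominates wrist dynamics.
#'
#' @inheritParams inverse_dynamics
#' @return An object of class `wrist_linear_model`: list with 2x2 matrices
#'   `M`, `B`, `K` and length-2 `gravity_bias` (Nm).
#' @export
linearize_model <- function(params, K, B) {
  stopifnot(inherits(params, "inertial_params"),
            inherits(K, "stiffness_tensor"),
            inherits(B, "damping_tensor"))
  M <- diag(c(params$Iw + params$Iz +
                params$m * params$rAC * (params$rAC + 2 * params$rCD),
              params$Ix))
  dimnames(M) <- list(c("beta", "gamma"), c("beta", "gamma"))
  structure(
    list(M = M, B = as.matrix(B), K = as.matrix(K),
         gravity_bias = c(beta = 0, gamma = -params$m * params$g * params$rCD)),
    class = "wrist_linear_model"
  )
}

#' @export
print.wrist_linear_model <- function(x, ...) {
  cat("wrist_linear_model: T = M qdd + B qd + K q + g0\n")
  cat(sprintf("  M = diag(%.4g, %.4g) kg.m^2, g0 = (0, %.4g) Nm\n",
              x$M[1, 1], x$M[2, 2], x$gravity_bias[2]))
  invisible(x)
}

#' Torques predicted by a linearized wrist model
#'
#' @param model a `wrist_linear_model` from [linearize_model()].
#' @param state a [wrist_state()] with accelerations.
#' @return Named numeric vector `c(T_b, T_g)` in Nm.
#' @export
linear_torque <- function(model, state) {
  stopifnot(inherits(model, "wrist_linear_model"),
            inherits(state, "wrist_state"))
  if (is.null(state$beta_ddot) || is.null(state$gamma_ddot)) {
    stop("linear_torque: state must carry accelerations", call. = FALSE)
  }
  q <- c(state$beta, state$gamma)
  qd <- c(state$beta_dot, state$gamma_dot)
  qdd <- c(state$beta_ddot, state$gamma_ddot)
  tt <- drop(model$M %*% qdd + model$B %*% qd + model$K %*% q) +
    model$gravity_bias
  c(T_b = tt[[1]], T_g = tt[[2]])
}
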