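# Independent oracle: literal symbol-for-symbol transcription of the
# universal-joint equations of motion, kept free of any package internals.
oracle_eq1 <- function(beta, gamma, beta_dot, gamma_dot, beta_ddot,
                       gamma_ddot, m, Ix, Iy, Iz, Iw, rAC, rCD, g,
                       Kbb, Kbg, Kgg, Bbb, Bbg, Bgg) {
  Tinert_b <- beta_ddot * (Iw + Iy * sin(gamma)^2 + Iz * cos(gamma)^2 +
                             m * rAC * (rAC + 2 * rCD * cos(gamma))) +
    beta_dot * gamma_dot * (2 * (Iy - Iz) * sin(gamma) * cos(gamma) -
                              2 * m * rAC * rCD * sin(gamma))
  Tinert_g <- gamma_ddot * Ix -
    beta_dot^2 * ((Iy - Iz) * sin(gamma) * cos(gamma) -
                    m * rAC * rCD * sin(gamma))
  Tdamp_b <- Bbb * beta_dot + Bbg * gamma_dot
  Tdamp_g <- Bgg * gamma_dot + Bbg * beta_dot
  Tstiff_b <- Kbb * beta + Kbg * gamma
  Tstiff_g <- Kgg * gamma + Kbg * beta
  Tgrav_g <- -m * g * rCD * cos(gamma)
  list(T_b = Tinert_b + Tdamp_b + Tstiff_b,
       T_g = Tinert_g + Tdamp_g + Tstiff_g + Tgrav_g,
       Tinert_b = Tinert_b, Tinert_g = Tinert_g)
}

test_that("only the gravity moment survives at rest in neutral posture", {
  p <- adult_params()
  s <- wrist_state(0, 0, 0, 0, 0, 0)
  td <- inverse_dynamics(s, p, stiffness_tensor(3, 0.5, 2),
                         damping_tensor(0.03))
  expect_identical(td$T_b, 0)
  expect_equal(td$T_g, -p$m * p$g * p$rCD)
  expect_equal(td$T_g, -0.24525)
})

test_that("a static deflection produces pure stiffness torques on both axes", {
  p <- adult_params(rCD = 0)
  s <- wrist_state(0.2, 0, 0, 0, 0, 0)
  td <- inverse_dynamics(s, p, stiffness_tensor(3, 0.5, 2),
                         damping_tensor(0))
  expect_equal(td$T_b, 0.6)
  expect_equal(td$T_g, 0.1)
  expect_equal(td$T_damp_b, 0)
  expect_equal(td$T_inert_b, 0)
})

test_that("inverse dynamics matches the term-by-term oracle transcription", {
  p <- adult_params()
  K <- adult_K()
  B <- build_damping_tensor(K)
  set.seed(42)
  for (i in 1:200) {
    s <- random_state()
    td <- inverse_dynamics(s, p, K, B)
    o <- oracle_eq1(s$beta, s$gamma, s$beta_dot, s$gamma_dot,
                    s$beta_ddot, s$gamma_ddot,
                    p$m, p$Ix, p$Iy, p$Iz, p$Iw, p$rAC, p$rCD, p$g,
                    K$Kbb, K$Kbg, K$Kgg, B$Bbb, B$Bbg, B$Bgg)
    expect_lt(abs(td$T_b - o$T_b), 1e-12 * max(1, abs(o$T_b)))
    expect_lt(abs(td$T_g - o$T_g), 1e-12 * max(1, abs(o$T_g)))
  }
})

test_that("totals equal the sum of their components exactly", {
  p <- adult_params()
  K <- adult_K()
  B <- build_damping_tensor(K)
  set.seed(7)
  for (i in 1:50) {
    td <- inverse_dynamics(random_state(), p, K, B)
    expect_identical(td$T_b, td$T_inert_b + td$T_damp_b + td$T_stiff_b)
    expect_identical(td$T_g,
                     td$T_inert_g + td$T_damp_g + td$T_stiff_g + td$T_grav_g)
  }
})

test_that("interaction torques vanish at gamma = 0 and when Iy = Iz with no offset", {
  K <- adult_K()
  B <- build_damping_tensor(K)
  p <- adult_params()
  set.seed(11)
  for (i in 1:20) {
    s <- wrist_state(runif(1, -0.5, 0.5), 0, runif(1, -3, 3),
                     runif(1, -3, 3), runif(1, -5, 5), runif(1, -5, 5))
    td <- inverse_dynamics(s, p, K, B)
    expect_equal(td$interaction_b, 0)
    expect_equal(td$interaction_g, 0)
  }
  p_sym <- inertial_params(m = 0.5, Ix = 1e-3, Iy = 1e-3, Iz = 1e-3,
                           rCD = 0.05, rAC = 0)
  for (i in 1:20) {
    td <- inverse_dynamics(random_state(), p_sym, K, B)
    expect_equal(td$interaction_b, 0)
    expect_equal(td$interaction_g, 0)
  }
})

test_that("state validation rejects non-finite and out-of-range entries", {
  expect_error(wrist_state(NaN, 0), "finite")
  expect_error(wrist_state(0, Inf), "finite")
  expect_error(wrist_state(3.5, 0), "pi")
  p <- adult_params()
  s <- wrist_state(0.1, 0.1)  # no accelerations
  expect_error(inverse_dynamics(s, p, adult_K(), damping_tensor(0.03)),
               "acceleration")
})

test_that("unforced equilibrium at neutral stays identically at rest", {
  p <- adult_params(rCD = 0)  # no gravity moment
  tr <- forward_simulate(wrist_state(0, 0), NULL, p, adult_K(),
                         build_damping_tensor(adult_K()),
                         dt = 1e-3, duration = 1)
  expect_true(all(tr$beta_rad == 0))
  expect_true(all(tr$gamma_rad == 0))
})

test_that("pure-FE release oscillates at the harmonic-oscillator frequency", {
  p <- adult_params(rCD = 0, rAC = 0)
  Kbb <- 3
  K <- stiffness_tensor(Kbb, 0, 50)  # RUD pinned stiff, uncoupled
  tr <- forward_simulate(wrist_state(0.1, 0), NULL, p, K,
                         damping_tensor(0), dt = 1e-4, duration = 2)
  m_beta <- p$Iw + p$Iz  # gamma remains 0
  f_theory <- sqrt(Kbb / m_beta) / (2 * pi)
  z <- which(diff(sign(tr$beta_rad)) != 0)
  f_meas <- 1 / (2 * mean(diff(tr$time_s[z])))
  expect_lt(abs(f_meas - f_theory) / f_theory, 0.01)
  expect_lt(max(abs(tr$gamma_rad)), 1e-12)
})

test_that("damped unforced motion dissipates energy monotonically", {
  p <- adult_params(rCD = 0)
  K <- adult_K()
  tr <- forward_simulate(wrist_state(0.2, -0.1), NULL, p, K,
                         damping_tensor(0.05, 0.01, 0.04),
                         dt = 1e-3, duration = 2)
  E <- wrist_energy(tr, p, K)
  expect_true(all(diff(E) <= 1e-10))
  expect_lt(E[length(E)], E[1])
})

test_that("simulation reports divergence and degenerate inertia as errors", {
  p <- adult_params()
  # negative stiffness blows the state up quickly
  expect_error(
    forward_simulate(wrist_state(0.1, 0), NULL, p,
                     stiffness_tensor(-500, 0, -500), damping_tensor(0),
                     dt = 1e-3, duration = 10),
    "diverged|non-finite|degenerate|missing value|t =", ignore.case = TRUE)
  expect_error(forward_simulate(wrist_state(0, 0), NULL, p, adult_K(),
                                damping_tensor(0), dt = -1, duration = 1),
               "dt")
})

test_that("linearized torques match nonlinear ones near neutral and diverge slowly", {
  p <- adult_params()
  K <- adult_K()
  B <- build_damping_tensor(K)
  lmod <- linearize_model(p, K, B)
  # exact at the expansion point
  s0 <- wrist_state(0, 0, 0, 0, 0, 0)
  t0 <- inverse_dynamics(s0, p, K, B)
  l0 <- linear_torque(lmod, s0)
  expect_equal(unname(l0[1]), t0$T_b)
  expect_equal(unname(l0[2]), t0$T_g)
  # within 5% of the per-axis torque scale over the moderate-rotation grid
  set.seed(3)
  diffs_b <- diffs_g <- tb <- tg <- numeric(500)
  for (i in 1:500) {
    s <- wrist_state(runif(1, -0.25, 0.25), runif(1, -0.25, 0.25),
                     runif(1, -1, 1), runif(1, -1, 1),
                     runif(1, -2, 2), runif(1, -2, 2))
    tn <- inverse_dynamics(s, p, K, B)
    tl <- linear_torque(lmod, s)
    diffs_b[i] <- tl[1] - tn$T_b
    diffs_g[i] <- tl[2] - tn$T_g
    tb[i] <- tn$T_b; tg[i] <- tn$T_g
  }
  expect_lt(max(abs(diffs_b)) / max(abs(tb)), 0.05)
  expect_lt(max(abs(diffs_g)) / max(abs(tg)), 0.05)
})

test_that("with Iy = Iz and no offsets the FE equation is exactly linear in any posture", {
  p <- inertial_params(m = 0.5, Ix = 1e-3, Iy = 1e-3, Iz = 1e-3,
                       rCD = 0, rAC = 0)
  K <- adult_K()
  B <- build_damping_tensor(K)
  lmod <- linearize_model(p, K, B)
  set.seed(5)
  for (i in 1:50) {
    s <- random_state()
    tn <- inverse_dynamics(s, p, K, B)
    tl <- linear_torque(lmod, s)
    expect_equal(unname(tl[1]), tn$T_b, tolerance = 1e-14)
  }
})

test_that("trajectory CSV round-trips through the interchange format", {
  p <- adult_params()
  K <- adult_K()
  tr <- forward_simulate(wrist_state(0.1, 0.05), NULL, p, K,
                         build_damping_tensor(K), dt = 1e-2, duration = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_s3_class(back, "wrist_trajectory")
  expect_equal(back$beta_rad, tr$beta_rad, tolerance = 1e-12)
  expect_equal(back$T_gamma_Nm, tr$T_gamma_Nm, tolerance = 1e-12)
})
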