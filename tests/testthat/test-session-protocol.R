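scripted_patient <- function(seed = 9, peak_torque = 1.5,
                             excursion_amp = 0.4) {
  virtual_patient(
    adult_params(), adult_K(), seed = seed,
    effort_script = function(t) peak_torque * sin(pi * t / 10)^2,
    fatigue_script = function(t) pmin(1, t / 30),
    excursion_script = function(t) excursion_amp * sin(2 * pi * t / 10))
}

test_that("the noiseless passive phase converges in two iterations with exact recovery", {
  vp <- virtual_patient(adult_params(), adult_K(), seed = 3)
  res <- run_passive_phase(vp, session_config(passive_noise_sd = 0))
  expect_true(res$converged)
  expect_equal(res$iterations, 2L)
  expect_lt(abs(res$K$Kbb - 3) / 3, 1e-9)
  expect_lt(abs(res$K$Kgg - 2) / 2, 1e-9)
  expect_identical(res$B$Bbb, 0.03)
})

test_that("the noisy passive phase converges within tolerance of the truth", {
  vp <- virtual_patient(adult_params(), adult_K(), seed = 14)
  # 20 dB SNR on the stiffness torque
  noise_sd <- adult_K()$Kbb * sd(seq(-0.3, 0.3, length.out = 201)) / 10
  res <- run_passive_phase(vp, session_config(passive_noise_sd = noise_sd))
  expect_lt(abs(res$K$Kbb - 3) / 3, 0.05)
  expect_lt(abs(res$K$Kgg - 2) / 2, 0.05)
})

test_that("an iteration cap of one returns unconverged after one iteration", {
  vp <- virtual_patient(adult_params(), adult_K(), seed = 3)
  res <- run_passive_phase(vp, session_config(passive_max_iter = 1))
  expect_equal(res$iterations, 1L)
  expect_false(res$converged)
})

test_that("the passive phase replays recorded trials supplied as a function", {
  x <- seq(-0.3, 0.3, length.out = 50)
  supplier <- function(iter) list(
    fe = passive_trial("FE", x, 3 * x),
    rud = passive_trial("RUD", x, 2 * x))
  res <- run_passive_phase(supplier, session_config())
  expect_true(res$converged)
  expect_equal(res$K$Kbb, 3, tolerance = 1e-9)
  expect_identical(res$K$Kbg, 0)
})

test_that("the resistive phase measures scripted effort and routes on readability", {
  vp <- scripted_patient(peak_torque = 1.5, excursion_amp = 0.4)
  res <- run_resistive_phase(vp, session_config())
  expect_equal(res$max_active_torque, 1.5, tolerance = 1e-6)
  expect_equal(res$rom_deg, 0.8 * 180 / pi, tolerance = 1e-6)
  expect_true(res$readable)
  expect_identical(res$next_phase, "BOTH_ACTIVE")

  limp <- virtual_patient(adult_params(), adult_K(), seed = 2)  # zero effort
  res0 <- run_resistive_phase(limp, session_config())
  expect_false(res0$readable)
  expect_identical(res0$next_phase, "PASSIVE_ROBOT_ACTIVE")
  expect_equal(res0$max_active_torque, 0)
})

test_that("fatigue attenuation of patient torque follows the clamped linear map", {
  expect_equal(resulting_patient_torque(1.0, 0, 2.0), 1.0)
  expect_equal(resulting_patient_torque(1.2, 0.5, 1.0), 0.7)
  expect_equal(resulting_patient_torque(0.8, 1, 1.0), 0)   # full attenuation
  expect_equal(resulting_patient_torque(-1.2, 0.5, 1.0), -0.7)  # sign kept
  # monotone non-increasing in fatigue
  lv <- seq(0, 1, by = 0.05)
  out <- resulting_patient_torque(rep(1.5, length(lv)), lv, 1.0)
  expect_true(all(diff(out) <= 1e-12))
  expect_true(all(abs(out) <= 1.5))
  expect_error(resulting_patient_torque(1, 1.5, 1), "\\[0, 1\\]")
})

test_that("the combined step splits required torque between robot and patient", {
  p <- adult_params()
  K <- adult_K()
  B <- build_damping_tensor(K)
  d <- wrist_state(0.2, -0.1, 0.5, 0.2, 1, -0.5)
  req <- inverse_dynamics(d, p, K, B)
  # passive patient: robot supplies everything
  s0 <- combined_phase_step(d, p, K, B)
  expect_equal(s0$robot_torque, c(req$T_b, req$T_g))
  # fresh patient covering the full requirement: robot torque zero
  s1 <- combined_phase_step(d, p, K, B,
                            patient_torque = c(req$T_b, req$T_g),
                            fatigue_level = 0,
                            max_active_torque = 2)
  expect_equal(s1$robot_torque, c(0, 0))
})

test_that("assist-as-needed tracking follows the desired trajectory closely", {
  vp <- scripted_patient()
  amp <- 0.3; f <- 0.25
  desired <- function(t) {
    w <- 2 * pi * f
    list(beta = amp * sin(w * t), gamma = 0,
         beta_dot = amp * w * cos(w * t), gamma_dot = 0,
         beta_ddot = -amp * w^2 * sin(w * t), gamma_ddot = 0)
  }
  res <- run_combined_phase(vp, desired, max_active_torque = 1.5,
                            config = session_config(combined_duration = 8))
  # RMS angle error under 2% of the movement amplitude
  expect_lt(res$rms_error_rad / amp, 0.02)
})

test_that("motor torque from current is the linear map", {
  expect_equal(torque_from_current(2, 0.5), 1.0)
  expect_equal(torque_from_current(0, 0.5), 0)
  expect_equal(torque_from_current(c(1, 2), 0.5),
               2 * torque_from_current(c(0.5, 1), 0.5))
  expect_error(torque_from_current(1, -0.5), "torque_constant")
})

test_that("rpf reproduces the worked ratings and is monotone and bounded", {
  expect_identical(rpf(45), 5.0)
  expect_identical(rpf(62), 6.8)
  expect_identical(rpf(72), 8.0)
  # truncation, not rounding: 62/90 would round to 6.9
  expect_lt(rpf(62), 6.9)
  # exactly representable ratios are not truncated a decimal down
  expect_identical(rpf(27), 3.0)
  expect_identical(rpf(81), 9.0)
  roms <- seq(0, 150, by = 0.5)
  vals <- rpf(roms)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 10))
  expect_identical(rpf(120), 10.0)  # capped
  expect_error(rpf(-5), "rom_deg")
  # configurable reference
  expect_identical(rpf(45, healthy_rom_table(reference_rom = 45)), 10.0)
})

test_that("reports echo single records and sort sessions chronologically", {
  r1 <- session_record("s1", "2021-02-22", "FE", "BOTH_ACTIVE",
                       rom_deg = 45, rpf = rpf(45),
                       passive_stiffness = 0.21, max_active_torque = 1.27)
  rep1 <- generate_report(list(r1))
  s <- rep1$subjects[["s1"]]
  expect_equal(s$sessions$rom_deg, 45)
  expect_equal(s$sessions$rpf, 5.0)
  expect_equal(s$sessions$stiffness_Nm_per_rad, 0.21)
  expect_equal(s$sessions$active_torque_Nm, 1.27)

  r0 <- session_record("s1", "2021-02-12", "FE", "PASSIVE_ROBOT_ACTIVE",
                       rom_deg = 30, rpf = rpf(30),
                       passive_stiffness = 0.26, max_active_torque = 0.93)
  rep2 <- generate_report(list(r1, r0))  # deliberately out of order
  expect_equal(rep2$subjects[["s1"]]$sessions$date,
               as.Date(c("2021-02-12", "2021-02-22")))
  expect_equal(rep2$subjects[["s1"]]$trend$rom_change_deg, 15)
  expect_error(generate_report(list()), "at least one")
})

test_that("the three-patient synthetic fixture reproduces the recovery narrative shape", {
  # endpoint-shaped fixtures: RoM up, stiffness down, active torque up
  fixture <- list(
    list(id = "patient1", dates = c("2021-02-12", "2021-02-22"),
         rom = c(30, 45), k = c(0.26, 0.21), tq = c(0.93, 1.27)),
    list(id = "patient2", dates = c("2021-02-27", "2021-03-09"),
         rom = c(40, 62), k = c(0.20, 0.13), tq = c(1.10, 1.72)),
    list(id = "patient3", dates = c("2020-03-19", "2020-03-29"),
         rom = c(50, 72), k = c(0.15, 0.09), tq = c(1.50, 2.09))
  )
  recs <- unlist(lapply(fixture, function(f) {
    lapply(1:2, function(i) {
      session_record(f$id, f$dates[i], "RUD",
                     if (i == 1) "PASSIVE_ROBOT_ACTIVE" else "BOTH_ACTIVE",
                     rom_deg = f$rom[i], rpf = rpf(f$rom[i]),
                     passive_stiffness = f$k[i], max_active_torque = f$tq[i])
    })
  }), recursive = FALSE)
  rep3 <- generate_report(recs)
  expect_length(rep3$subjects, 3)
  for (s in rep3$subjects) {
    expect_gt(s$trend$rom_change_deg, 0)
    expect_lt(s$trend$stiffness_change, 0)
    expect_gt(s$trend$torque_change, 0)
  }
  expect_equal(rep3$subjects[["patient1"]]$sessions$rpf[2], 5.0)
  expect_equal(rep3$subjects[["patient2"]]$sessions$rpf[2], 6.8)
  expect_equal(rep3$subjects[["patient3"]]$sessions$rpf[2], 8.0)
  # JSON serialization is stable and re-readable
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep3, path)
  doc <- jsonlite::read_json(path)
  expect_length(doc$subjects, 3)
  expect_equal(doc$subjects[[1]]$sessions[[2]]$rom_deg, 45)
})

test_that("a full session reaches the combined phase only with readable torque", {
  vp <- scripted_patient()
  out <- run_session(vp, session_config(), date = "2021-02-22")
  expect_identical(out$record$phase, "BOTH_ACTIVE")
  expect_equal(out$record$max_active_torque, 1.5, tolerance = 1e-6)
  expect_lt(abs(out$record$passive_stiffness - 3) / 3, 1e-6)
  expect_equal(out$record$rom_deg, 0.8 * 180 / pi, tolerance = 1e-6)
  expect_identical(out$record$rpf, rpf(0.8 * 180 / pi))
  # estimated fatigue rises over the combined phase
  ft <- out$fatigue_trace
  expect_gt(mean(utils::tail(ft$fatigue, 6)), mean(utils::head(ft$fatigue, 6)))

  limp <- virtual_patient(adult_params(), adult_K(), seed = 4)
  out0 <- run_session(limp, session_config(), date = "2021-02-22")
  expect_identical(out0$record$phase, "PASSIVE_ROBOT_ACTIVE")
  expect_null(out0$fatigue_trace)
  # clinician override unlocks the combined phase despite unreadable torque
  out1 <- run_session(limp, session_config(allow_combined_override = TRUE),
                      date = "2021-02-22")
  expect_identical(out1$record$phase, "BOTH_ACTIVE")
})
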