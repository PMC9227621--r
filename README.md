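# wristdyn

Computational tools for **assist-as-needed robotic wrist rehabilitation**.
The package is aimed at rehabilitation-robotics engineers and biomechanics
researchers who need the full signal chain of an EMG-aware wrist therapy
protocol in one reproducible place: a mechanical impedance model of the
wrist, subject-specific parameter identification, EMG fatigue monitoring,
and the three-phase exercise protocol with session scoring — all runnable
against a synthetic virtual patient, so no recorded data are required.

## The model

The wrist is treated as a universal joint with two degrees of freedom —
flexion–extension (FE, angle β about the forearm-fixed Z axis) and
radial–ulnar deviation (RUD, angle γ) — whose axes do not intersect but are
offset by r_AC. The torque required about each axis decomposes into
inertial, damping, stiffness and (for RUD) gravity components:

```
T_β = T_inert,β + T_damp,β + T_stiff,β
T_γ = T_inert,γ + T_damp,γ + T_stiff,γ + T_grav,γ

T_inert,β = β̈ [I_w + I_y sin²γ + I_z cos²γ + m r_AC (r_AC + 2 r_CD cos γ)]
            + β̇ γ̇ [2 (I_y − I_z) sin γ cos γ − 2 m r_AC r_CD sin γ]
T_inert,γ = γ̈ I_x − β̇² [(I_y − I_z) sin γ cos γ − m r_AC r_CD sin γ]
T_damp,β  = B_ββ β̇ + B_βγ γ̇        T_damp,γ  = B_γγ γ̇ + B_βγ β̇
T_stiff,β = K_ββ β + K_βγ γ         T_stiff,γ = K_γγ γ + K_βγ β
T_grav,γ  = − m g r_CD cos γ
```

The second (velocity-product) inertial terms are *interaction torques*:
torque on one axis caused by motion of the other. Because wrist dynamics
are stiffness-dominated, the model linearizes well for moderate rotations
(`linearize_model()`), which is what makes a simple internal model viable
for torque control.

Around the plant model the package provides:

- **Parameter estimation** — inertial parameters from anthropometry via a
  documented ellipsoidal hand model; passive stiffness as the OLS slope of
  torque–displacement ramps; the damping tensor by proportional scaling
  calibrated to 0.03 Nms/rad in pure FE.
- **EMG fatigue features** — Welch power spectra and the four
  frequency-domain features MNF (mean frequency), MNP (mean power), FR
  (low/high frequency ratio) and PSR (power near the spectral peak over
  total power).
- **Fuzzy fatigue classifier** — Mamdani inference with Gaussian
  membership functions, min-AND, max-aggregation and Centre-of-Area
  defuzzification, over a serializable (YAML) rule base.
- **Session protocol** — the three phases (robot-active/patient-passive
  identification → patient-active/robot-resistive capacity test →
  combined assist-as-needed exercise), fatigue-attenuated torque sharing,
  RoM scoring on the ten-point RPF scale, and JSON session reports.
- **Virtual patient** — seeded generators for passive trials, scripted
  effort, and fatiguing EMG with controlled spectral compression.

## Worked example

A complete session on a scripted virtual patient with known stiffness
(K_ββ = 3, K_βγ = 0.4, K_γγ = 2 Nm/rad), a 1.5 Nm peak effort and a ±0.4
rad exercise sweep:

```r
library(wristdyn)

params <- inertial_from_anthropometry(anthropometry(0.19, 0.26, 0.45, "demo"))
K_true <- stiffness_tensor(Kbb = 3, Kbg = 0.4, Kgg = 2)
vp <- virtual_patient(
  params, K_true, seed = 42, subject_id = "demo",
  effort_script    = function(t) 1.5 * sin(pi * t / 10)^2,
  fatigue_script   = function(t) pmin(1, t / 30),
  excursion_script = function(t) 0.4 * sin(2 * pi * t / 10))

out <- run_session(vp, session_config(), date = "2021-02-22")
print(out$record)
#> session_record demo 2021-02-22 [FE, BOTH_ACTIVE]: RoM 45.8 deg, RPF 5.0, K 3 Nm/rad, T_max 1.5 Nm
ft <- out$fatigue_trace
cat(sprintf("fatigue estimate: %.2f -> %.2f\n",
            ft$fatigue[1], ft$fatigue[nrow(ft)]))
#> fatigue estimate: 0.16 -> 0.50
```

What the numbers mean: the passive phase converged in 2 iterations and
recovered the plant stiffness exactly (K_ββ = 3 Nm/rad); the patient's
scripted ±0.4 rad sweep is an RoM of 45.8°, which rates 5.0 on the
ten-point RPF scale against the 90° healthy reference; the peak active
torque was 1.5 Nm; and the EMG-based fuzzy classifier tracked the scripted
fatigue ramp from a fresh 0.16 up to 0.50 over the 30 s combined phase, so
the robot progressively takes over torque the fatigued patient can no
longer supply.

A command-line interface wrapping the same functions ships in
`exec/wristdyn` (subcommands `simulate`, `invdyn`, `estimate`,
`emg-features`, `fatigue`, `synth`).

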