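---
title: "Methods: wrist impedance modelling and EMG-aware session protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist impedance modelling and EMG-aware session protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristdyn)
```

## The mechanical model and its assumptions

`wristdyn` models the wrist as a universal joint with two rotational
degrees of freedom: flexion–extension (FE, angle $\beta$ about the
forearm-fixed $Z$ axis) and radial–ulnar deviation (RUD, angle $\gamma$
about the rotated $x$ axis). The two axes do not intersect; their
perpendicular offset $r_{AC}$ defaults to 4 mm, the same value for every
subject. The torque required about each axis is the sum of inertial,
damping, stiffness and (on the RUD axis) gravitational components; the FE
inertia coefficient $M_\beta(\gamma) = I_w + I_y\sin^2\gamma +
I_z\cos^2\gamma + m\,r_{AC}(r_{AC} + 2 r_{CD}\cos\gamma)$ depends on the
RUD posture, and velocity-product *interaction* torques couple the axes.
The damping and stiffness couplings ($B_{\beta\gamma}$,
$K_{\beta\gamma}$) are independent of the axis offset: they arise because
the passive force field of the wrist is not aligned with either rotation
axis.

Assumptions worth keeping in mind:

- **Posture.** The gravity term $-m g\, r_{CD}\cos\gamma$ acts only on
  the RUD axis. This fixes the modelled posture as forearm horizontal and
  pronated, neutral at $\beta = \gamma = 0$, flexion and radial deviation
  positive. Other arm postures would need a different gravity map.
- **Pure plant.** Muscle torques enter only as the applied torque pair;
  there is no muscle model (no activation dynamics, no force–length
  properties) and no third degree of freedom (pronation–supination).
- **Linearity in the passive field.** Stiffness and damping are constant
  symmetric $2\times2$ tensors. Real passive wrist stiffness stiffens
  toward the range limits; the linear model is a mid-range approximation,
  which is also why stiffness is *estimated* as a straight-line slope.
- **Rigid hand.** The hand is a single rigid body with its centre of
  mass $r_{CD}$ distal of the joint; $I_w$ (wrist-link inertia) is small
  against $I_z$ and defaults to 0, but remains settable.

The model is energy-consistent: it derives from a Lagrangian with kinetic
energy $\tfrac12 M_\beta(\gamma)\dot\beta^2 + \tfrac12 I_x\dot\gamma^2$,
elastic energy of the stiffness tensor, and gravitational potential
$-m g r_{CD}\sin\gamma$. `wrist_energy()` evaluates this invariant, and
the test suite uses it as an integrator check: unforced, undamped motion
conserves it; damped motion dissipates it monotonically.

Because stiffness, not inertia, dominates wrist rotation dynamics, the
small-angle model from `linearize_model()` (with
$\sin\gamma \to \gamma$, $\cos\gamma \to 1$, velocity products dropped)
tracks the full model to well under 5% of the torque scale for
$|\beta|,|\gamma| \le 0.25$ rad and rates up to 1 rad/s. Note the error
is quoted against the per-axis torque *scale* (the largest torque seen on
the evaluation grid), not pointwise: any approximation has unbounded
pointwise relative error where the true torque crosses zero.

## Numerical choices

- **Integration.** `forward_simulate()` integrates the explicit ODE (the
  system is solvable for the accelerations since $M_\beta(\gamma) > 0$
  and $I_x > 0$) with deSolve's fixed-step classical Runge–Kutta scheme,
  default `dt` 1 ms. An adaptive high-accuracy option (`method =
  "lsoda"`, rtol 1e-10) exists for reference runs. Returned trajectories
  carry the instantaneous accelerations implied by the plant, so inverse
  dynamics along a simulated trajectory reproduces the applied torque to
  round-off — a deliberate algebraic identity used as a pipeline check.
- **Degenerate inputs.** A non-finite state aborts integration with the
  failing time in the message; $M_\beta(\gamma) \le 0$ (possible only
  with unphysical parameters) is a distinct degenerate-inertia error.
- **Units.** Radians and SI everywhere inside the package; degrees appear
  only in RoM reporting (`rom_deg`, RPF), where clinical convention
  expects them.
- **RPF truncation.** The ten-point rating is `10 * rom/reference`
  truncated (not rounded) to one decimal — 62° against 90° is 6.888…,
  reported as 6.8. The implementation adds 1e-9 before flooring so that
  ratios that are exact in decimal but not in binary (27/90 → 3.0) do not
  truncate a decimal too low. The 90° reference reproduces all three
  worked ratings (45° → 5.0, 62° → 6.8, 72° → 8.0) and is configurable
  per movement; note 90° exceeds the healthy radial+ulnar range in the
  reference table, so for RUD exercises a clinician may prefer a smaller
  denominator.

## Parameter estimation

- **Inertial parameters** come from anthropometry: the hand is a solid
  homogeneous ellipsoid with semi-axes fixed fractions of hand length
  (`anthro_coefficients()`: 0.5 longitudinal, 0.22 medio-lateral, 0.12
  dorso-palmar, centre of mass at 0.506 of hand length). These
  coefficients are deliberately exposed as data, not buried as constants:
  any segment-inertia regression from the anthropometric literature can
  be substituted via the `coeffs` argument, and the shipped values are a
  documented default of the expected order of magnitude (≈1e-3 kg·m²
  for an adult hand), not a clinical calibration.
- **Passive stiffness** is the least-squares slope of torque on
  displacement from slow robot-imposed ramps, fitted *with* an intercept:
  the intercept absorbs sensor bias and the constant damping offset of a
  constant-velocity sweep, leaving the slope an unbiased stiffness
  estimate. The cross term $K_{\beta\gamma}$ is the mean of the two
  cross-axis slopes when the orthogonal torque was recorded, else 0 — the
  estimation protocol for the cross term was genuinely open, and the
  averaged-slope choice keeps the estimate symmetric by construction.
- **Damping** is not identified from data; it is proportional to the
  stiffness tensor, scaled so the pure-FE element is exactly 0.03
  Nms/rad. `build_damping_tensor()` therefore returns `Bbb = 0.03`
  bit-exactly, a property the tests assert as an identity.
- Stiffness is Nm/rad internally. Clinical summaries sometimes print
  stiffness in "Nm"; dimensionally a slope of torque over angle is
  Nm/rad, and the package reports it as such.

## EMG features and the fatigue classifier

`compute_psd()` is a Welch averaged periodogram: 1 s Hann-tapered,
mean-detrended segments at 50% overlap, one-sided, scaled so the summed
bin powers approximate the signal variance. No bandpass or notch is
applied by default (`emg_preprocess()` offers a 20–450 Hz bandpass and a
mains notch for recorded data); synthetic EMG needs neither.

The four features per window are MNF ($\sum f_j P_j / \sum P_j$), MNP
($\sum P_j / M$), FR (low-band over high-band power) and PSR (power
within $\pm n$ bins of the peak bin over total power, $n$ set as ±10 Hz
at the spectrum's resolution; ties at the peak resolve to the
lowest-frequency bin). FR defaults to *MNF-split* bands — low below the
spectrum's own mean frequency, high at or above it — because the split
needs no per-subject band calibration; fixed experimental bands remain
available via `fr_bands(mode = "fixed")`. A self-referential split makes
FR nearly shift-invariant, so in the default configuration fatigue
tracking is carried mainly by MNF, MNP and PSR; the FR rules still enter
the rule base in their physiological direction and become informative
when fixed bands are configured.

The classifier is a standard Mamdani engine: Gaussian membership
functions, min for AND, clipping implication, max aggregation, and
Centre-of-Area defuzzification on a 1001-point grid over the [0, 1]
output range (the tests check this grid against a 10×-refined brute-force
centroid to 1e-3). Features are normalized by their mean over the first
5 windows of the session, making the classifier subject-relative: fresh
muscle sits near 1 on every axis. Crisp inputs are clamped to each
variable's term span before fuzzification so the extreme terms saturate
instead of decaying in their Gaussian tails — without clamping, a
monotone physiological trend would eventually *reverse* the inferred
fatigue once the input left the calibrated span. If no rule fires above
1e-6, the engine returns the mid-scale level 0.5 with a warning rather
than erroring mid-session.

The shipped `default_rule_base()` — three terms per variable, twelve
single-antecedent rules encoding MNF↓, PSR↓, MNP↑, FR↑ ⇒ fatigue↑ — is an
editable, serializable working configuration (YAML via
`write_rule_base()`), designed so that fresh-baseline inputs map below
0.2 and each single-feature sweep is monotone in its physiological
direction. It is explicitly a package default, not a claim about any
particular clinical rule table, which is why it is first-class data
rather than code.

## The virtual patient and what passing tests do (and do not) show

The synthetic generators exist so every stage is testable against known
ground truth:

- `synth_passive_trial()` sweeps the plant symmetrically
  (−amplitude…+amplitude) at constant speed and records exact inverse
  -dynamics torques plus seeded Gaussian noise. The symmetric design
  makes the even gravity term contribute exactly zero to the fitted
  slope, and the constant damping offset lands in the intercept — so
  noiseless trials recover the stiffness tensor to round-off, and the
  identification loop is validated end to end. A quasi-static check
  (characteristic reversal torque $M\,\omega^2/\text{amplitude}$ below 1%
  of peak stiffness torque) flags too-fast sweeps.
- `synth_emg()` shapes seeded white noise with a time-varying two-pole
  resonator whose centre frequency is `base_mnf + mnf_drift * fatigue(t)`
  (defaults 95 Hz and −40 Hz at fs = 1000 Hz, 20 Hz bandwidth), scaled by
  `amp_gain^fatigue(t)` (default 1.5) over a 5% white noise floor. This
  reproduces the *spectral* phenomenology of fatigue — compression toward
  low frequencies, amplitude growth — not its physiology: there are no
  motor-unit action potentials, no firing statistics, no electrode or
  crosstalk effects. Passing fatigue-detection tests therefore shows the
  feature–classifier chain responds correctly to spectral compression;
  it does not validate the classifier on real EMG.
- The resistive phase *measures* the patient's scripted effort and
  excursion rather than simulating the contested motion; contact dynamics
  between robot and limb are out of scope throughout.

All generators are pure functions of (configuration, seed), and session
-level seeds derive from the patient's single seed, so full sessions are
byte-reproducible.

## Protocol details

The passive phase repeats ramp-and-estimate iterations until both
diagonal stiffness elements change by less than 2% between successive
iterations, capped at 12 iterations (the cap mirrors the exercise-set
count used clinically); noiseless plants converge in 2 iterations by
construction. The resistive phase declares torque "readable" above 0.1 Nm
(configurable); an unreadable result routes the session back to passive
exercise, and the combined phase is reachable only after a readable
resistive phase or an explicit clinician override flag. In the combined
phase the robot command is the inverse-dynamics torque of the desired
state minus the fatigue-attenuated patient torque
$T_\text{eff} = \mathrm{sign}(T)\,\max(0, |T| - \text{fatigue}\cdot
g\cdot T_\text{max})$ — the fatigue-to-torque mapping is a design choice
(linear attenuation of measured capacity, gain $g$ default 1,
configurable), since only the subtraction structure is fixed by the
control architecture. Reports are flat JSON per subject with
chronologically sorted sessions and first-to-last trends; no database
engine is involved.

## Problem sizes used in the shipped tests

The test suite validates the dynamics oracle at 1000 random states,
energy conservation over 5 s at dt = 1e-4 s, stiffness recovery over 500
noisy replicates at 20 dB SNR, the CoA oracle at 100 random inputs, and
fatigue detection over 100 seeded 30 s EMG records — sizes chosen so the
whole suite completes in about a minute on one core while leaving the
statistical checks well-powered.

## Known limitations

- Two DOF only; no pronation–supination, no muscle-level modelling, no
  robot-structure or contact dynamics.
- Constant tensors: no stiffening toward range limits, no
  damping identification from free oscillation.
- The fuzzy rule base and membership parameters are package defaults;
  real deployments should recalibrate them per electrode montage and
  population, via the YAML interface.
- The EMG generator's spectral realism is sufficient for the classifier
  but not for validating electrode placement, crosstalk or notch
  filtering decisions.
- Telemetry schemas (desired position/torque out, position/current/EMG
  features back) are documented as JSON payloads, but no transport layer
  is included.
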