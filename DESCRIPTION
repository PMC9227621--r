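Package: wristdyn
Title: Wrist Impedance Modelling, EMG Fatigue Features and Robotic
    Rehabilitation Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assist-as-needed robotic wrist rehabilitation.
    Implements a two degree-of-freedom universal-joint impedance model of
    wrist rotations (inverse dynamics, forward simulation and small-angle
    linearization), subject-specific parameter estimation (anthropometric
    inertial parameters, passive stiffness from force-displacement trials,
    proportional damping), frequency-domain surface-EMG fatigue features
    (mean frequency, mean power, frequency ratio, power spectrum ratio), a
    Mamdani fuzzy classifier with Gaussian membership functions and
    centre-of-area defuzzification for fatigue estimation, and a
    three-phase rehabilitation session protocol with range-of-motion
    scoring and reporting. Includes a virtual-patient generator producing
    passive trials, scripted active-effort profiles and fatiguing EMG so
    the full pipeline runs without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
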