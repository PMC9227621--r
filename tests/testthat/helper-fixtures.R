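# Standard adult hand/wrist parameter set used across tests: ~0.5 kg hand,
# ellipsoid-scale inertias, CoM 5 cm distal of the wrist axes.
adult_params <- function(rCD = 0.05, rAC = 0.004, Iw = 0) {
  inertial_params(m = 0.5, Ix = 1e-3, Iy = 1.2e-3, Iz = 8e-4,
                  rCD = rCD, rAC = rAC, Iw = Iw)
}

adult_K <- function() stiffness_tensor(Kbb = 3, Kbg = 0.4, Kgg = 2)

# Toy 4-bin spectrum with hand-checkable feature values.
toy_spectrum <- function() power_spectrum(c(10, 20, 30, 40), c(1, 2, 3, 4))

random_state <- function() {
  wrist_state(stats::runif(1, -0.6, 0.6), stats::runif(1, -0.6, 0.6),
              stats::runif(1, -3, 3), stats::runif(1, -3, 3),
              stats::runif(1, -10, 10), stats::runif(1, -10, 10))
}

random_pd_stiffness <- function() {
  repeat {
    K <- stiffness_tensor(stats::runif(1, 0.5, 5), stats::runif(1, -1, 1),
                          stats::runif(1, 0.5, 5))
    if (K$Kbb * K$Kgg - K$Kbg^2 > 0) return(K)
  }
}
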