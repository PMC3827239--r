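# Independent oracles used across the suite.

R_GAS_ORACLE <- 0.082057338

# Forward headspace partitioning by root finding: given a true dissolved
# concentration, find the equilibrium headspace mixing ratio by driving the
# mole balance to zero with uniroot. Independent of the closed-form
# expressions inside the package.
oracle_equilibrate_ppm <- function(kh, c0_uM, vw_L, vh_L, temp_C,
                                   ppm_air, pressure = 1) {
  t_k <- temp_C + 273.15
  total_mol <- c0_uM * 1e-6 * vw_L +
    ppm_air * 1e-6 * pressure * vh_L / (R_GAS_ORACLE * t_k)
  balance <- function(p_eq) {
    kh * p_eq * vw_L + p_eq * vh_L / (R_GAS_ORACLE * t_k) - total_mol
  }
  root <- uniroot(balance, c(0, 10), tol = 1e-15)$root
  root / pressure * 1e6
}

# van 't Hoff Henry constant, written out independently
oracle_kh <- function(kh_ref, coef, temp_C) {
  kh_ref * exp(coef * (1 / (temp_C + 273.15) - 1 / 298.15))
}

# draw a random valid headspace scenario
random_headspace_case <- function(species) {
  list(
    c0 = runif(1, 0.05, 300),
    vw = runif(1, 0.5, 3),
    vh = runif(1, 0.005, 0.1),
    temp = runif(1, 1, 25),
    ppm_air = if (species$name == "CO2") 390 else 1.8
  )
}
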