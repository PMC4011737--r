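# shared helpers: unit shortcuts, toy systems and randomized physical
# parameter draws (generated in code; no stored fixtures)

mVs <- membranepb:::.mV_to_statV
smV <- membranepb:::.statV_to_mV
CST <- physical_constants()

# a charge-free, field-free symmetric toy: the flat profile psi == 0
# solves the whole system exactly
toy_symmetric <- function() {
  model_inputs(cell_name = "toy0", mobility = 0, sigma1 = 0, sigma2 = 0,
               sigma3 = 0, rho_f_g = 0, rho_f_c = 0,
               transmembrane_potential = 0)
}

# mildly charged toy with a unique root structure (no glycocalyx volume
# charge, no S1 charge, zero mobility)
toy_charged <- function(sigma2 = -800, sigma3 = -1500, rho_f_c = -1e7,
                        dpsi_mV = -60) {
  model_inputs(cell_name = "toy", mobility = 0, sigma1 = 0, sigma2 = sigma2,
               sigma3 = sigma3, rho_f_g = 0, rho_f_c = rho_f_c,
               transmembrane_potential = mVs(dpsi_mV))
}

# one randomized, physically plausible parameter draw; assumes the RNG
# seed has been fixed by the caller.  sigma1 is drawn as a fraction of
# the diffuse-layer field at S1 so the glycocalyx entry field stays
# moderate and the surface system stays solvable.
random_inputs <- function() {
  mono <- runif(1, 1.0e-4, 2.5e-4)
  div_e <- runif(1, 0, 4e-6)
  div_c <- runif(1, 0, 1e-6)
  psi1_mV <- runif(1, -25, -3)
  mobility <- 81 * mVs(psi1_mV) / (4 * pi)
  inp <- model_inputs(cell_name = "draw", mobility = mobility,
                      mono_e = mono, div_e = div_e,
                      mono_g = mono, div_g = div_e,
                      mono_c = mono, div_c = div_c,
                      sigma1 = 0, sigma2 = runif(1, -3000, -400),
                      sigma3 = runif(1, -4000, -500),
                      rho_f_g = runif(1, -2e9, 0),
                      rho_f_c = runif(1, -3e7, 0),
                      transmembrane_potential = mVs(runif(1, -90, -40)))
  # cancel most of the diffuse-layer field with sigma1
  cs <- membranepb:::.coef_set(inp)
  Ee1 <- membranepb:::.field_e_S1(inp$ions$g$psi_bound, cs$e, inp$constants)
  frac <- runif(1, 0.9, 1.0)
  inp$charges$sigma1 <- -frac * 81 * Ee1 / (4 * pi)
  inp
}

expect_rel_equal <- function(object, expected, tol = 1e-10) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-300), tol)
}
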