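test_that("first-integral constants reproduce their defining conditions", {
  set.seed(7)
  for (i in 1:100) {
    mono <- runif(1, 1e-5, 5e-4)
    div <- runif(1, 0, 5e-6)
    eps <- runif(1, 40, 100)
    # extracellular: zero slope at the bulk value 0
    ce <- region_coefficients(list(mono = mono, div = div, psi_bound = 0),
                              0, eps, CST, region = "e")
    Ke <- extracellular_constant(ce, 0, CST)
    s2 <- membranepb:::.pb_energy(0, ce, CST) + Ke$K
    scale <- membranepb:::.pb_energy_scale(0, ce, CST)
    expect_lt(abs(s2) / scale, 1e-10)
    # cytoplasm: zero slope at the transmembrane potential, with rho_fc
    dpsi <- mVs(runif(1, -90, 40))
    cc <- region_coefficients(list(mono = mono, div = div, psi_bound = dpsi),
                              runif(1, -5e10, 0), eps, CST, region = "c")
    Kc <- cytoplasm_constant(cc, dpsi, CST)
    expect_lt(abs(membranepb:::.pb_energy(dpsi, cc, CST) + Kc$K) /
                membranepb:::.pb_energy_scale(dpsi, cc, CST), 1e-10)
    # glycocalyx: reproduces the supplied anchor field exactly
    psi2 <- mVs(runif(1, -60, 0))
    field <- runif(1, -500, 500)
    cg <- region_coefficients(list(mono = mono, div = div,
                                   psi_bound = mVs(runif(1, -30, 0))),
                              runif(1, -5e10, 0), eps, CST, region = "g")
    Kg <- glycocalyx_constant(psi2, field, cg, CST)
    resid <- membranepb:::.pb_energy(psi2, cg, CST) + Kg$K - field^2
    expect_lt(abs(resid) / (membranepb:::.pb_energy_scale(psi2, cg, CST) +
                              field^2), 1e-10)
  }
})

test_that("degenerate and symmetric constant constructions behave", {
  ce <- region_coefficients(list(mono = 0, div = 0, psi_bound = 0),
                            0, 81, CST, region = "e")
  expect_error(extracellular_constant(ce, 0, CST), "unphysical")
  # rho_fc = 0 and zero bulk potential: cytoplasmic construction equals
  # the extracellular one with the same coefficients
  co <- region_coefficients(list(mono = 1.54e-4, div = 2e-6, psi_bound = 0),
                            0, 81, CST, region = "c")
  ce2 <- region_coefficients(list(mono = 1.54e-4, div = 2e-6, psi_bound = 0),
                             0, 81, CST, region = "e")
  expect_equal(cytoplasm_constant(co, 0, CST)$K,
               extracellular_constant(ce2, 0, CST)$K)
})

test_that("slope matches the Gouy-Chapman derivative and flags bad branches", {
  ce <- region_coefficients(list(mono = 1.54e-4, div = 0, psi_bound = 0),
                            0, 81, CST, region = "e")
  Ke <- extracellular_constant(ce, 0, CST)
  ode <- region_ode("e", ce, Ke, slope_sign = -1,
                    boundary_point = list(x = 0, psi = mVs(-50)),
                    constants = CST)
  # slope at the defining boundary value is zero
  expect_identical(slope(ode, 0), 0)
  # analytic derivative of the closed form at 20 grid points
  lam <- membranepb:::debye_length(list(mono = 1.54e-4, div = 0), 81, CST)
  kT <- CST$boltzmann_k * CST$temperature_T
  q <- CST$electron_charge_q
  gam <- tanh(q * mVs(-50) / (4 * kT))
  xg <- seq(0, 8 * lam, length.out = 20)
  psi <- (4 * kT / q) * atanh(gam * exp(-xg / lam))
  dpsi <- (4 * kT / q) * (-gam / lam) * exp(-xg / lam) /
    (1 - (gam * exp(-xg / lam))^2)
  got <- slope(ode, psi)   # rising branch toward 0: dpsi/dx < 0 here
  expect_lt(max(abs(abs(got) - abs(dpsi)) / abs(dpsi)), 1e-6)
  # a potential past the turning point is rejected
  cg <- region_coefficients(list(mono = 1.54e-4, div = 0, psi_bound = 0),
                            -1e10, 81, CST, region = "g")
  Kg <- glycocalyx_constant(0, 10, cg, CST)
  odeg <- region_ode("g", cg, Kg, slope_sign = -1,
                     boundary_point = list(x = 0, psi = 0), constants = CST)
  expect_error(slope(odeg, mVs(-0.5)), "reachable branch")
})

test_that("bilayer profile is the exact chord", {
  geo <- model_inputs()$geometry
  psi2 <- mVs(-25)
  psi3 <- mVs(-80)
  expect_identical(bilayer_profile(psi2, psi3, geo, geo$x_S2), psi2)
  expect_identical(bilayer_profile(psi2, psi3, geo, geo$x_S3), psi3)
  mid <- (geo$x_S2 + geo$x_S3) / 2
  expect_equal(bilayer_profile(psi2, psi3, geo, mid), (psi2 + psi3) / 2)
  expect_identical(bilayer_profile(psi2, psi2, geo, mid), psi2)
  expect_error(bilayer_profile(psi2, psi3, geo, geo$x_S3 + 1e-8),
               "outside the bilayer")
})
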