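make_gc_ode <- function(psi0_mV) {
  ce <- region_coefficients(list(mono = 1.54e-4, div = 0, psi_bound = 0),
                            0, 81, CST, region = "e")
  Ke <- extracellular_constant(ce, 0, CST)
  region_ode("e", ce, Ke, slope_sign = if (psi0_mV < 0) 1 else -1,
             boundary_point = list(x = 0, psi = mVs(psi0_mV)),
             constants = CST)
}

gc_closed_form <- function(psi0_mV, x) {
  kT <- CST$boltzmann_k * CST$temperature_T
  q <- CST$electron_charge_q
  lam <- membranepb:::debye_length(list(mono = 1.54e-4, div = 0), 81, CST)
  gam <- tanh(q * mVs(psi0_mV) / (4 * kT))
  (4 * kT / q) * atanh(gam * exp(-x / lam))
}

test_that("RK4 integration: constant solution and order of accuracy", {
  # zero-slope ODE at its bulk value stays constant
  ce <- region_coefficients(list(mono = 1.54e-4, div = 2e-6, psi_bound = 0),
                            0, 81, CST, region = "e")
  Ke <- extracellular_constant(ce, 0, CST)
  ode0 <- region_ode("e", ce, Ke, slope_sign = 1,
                     boundary_point = list(x = 0, psi = 0), constants = CST)
  out <- integrate_region(ode0, 0, 1e-6, 50)
  expect_identical(out$psi, rep(0, 51))
  expect_identical(nrow(out), 51L)

  # halving the step shrinks the error ~16x (4th order)
  ode <- make_gc_ode(-50)
  lam <- membranepb:::debye_length(list(mono = 1.54e-4, div = 0), 81, CST)
  L <- 5 * lam
  err <- function(n) {
    s <- integrate_region(ode, 0, L, n)
    max(abs(s$psi - gc_closed_form(-50, s$x)))
  }
  ratio <- err(50) / err(100)
  expect_gt(ratio, 10)
  expect_lt(ratio, 25)
})

test_that("integrated diffuse layer matches the closed form at n = 1000", {
  lam <- membranepb:::debye_length(list(mono = 1.54e-4, div = 0), 81, CST)
  s <- integrate_region(make_gc_ode(-50), 0, 10 * lam, 1000)
  expect_lt(max(abs(s$psi - gc_closed_form(-50, s$x))), 1e-6 * abs(mVs(-50)))
})

test_that("the symmetric toy assembles to the identically zero profile", {
  toy <- toy_symmetric()
  sol <- solve_surface_potentials(toy)
  prof <- assemble_profile(toy, sol, n_steps = 200)
  expect_identical(max(abs(prof$samples$psi)), 0)
})

test_that("preset profiles satisfy their boundary contracts", {
  inp <- load_preset("ganglion", "resting")
  sol <- solve_surface_potentials(inp)
  prof <- assemble_profile(inp, sol)
  s <- prof$samples
  # psi at S3 equals psi3 exactly (anchor)
  expect_identical(s$psi[s$x == prof$interfaces[["x_S3"]]], sol$psi3)
  # far cytoplasm within 0.1% of the resting transmembrane potential
  dpsi <- inp$state$transmembrane_potential
  expect_lt(abs(s$psi[nrow(s)] - dpsi) / abs(dpsi), 1e-3)
  # resting state: the inner surface sits below the bulk cytoplasmic value
  expect_lt(sol$psi3, dpsi)
  # validation passes wholesale
  rep <- validate_profile(prof, inp)
  expect_true(all(rep$table$pass))
})

test_that("a corrupted sample is caught and located by validate_profile", {
  inp <- load_preset("ganglion", "resting")
  sol <- solve_surface_potentials(inp)
  prof <- assemble_profile(inp, sol, n_steps = 500)
  k <- which(prof$samples$region == "c")[100]
  prof$samples$psi[k] <- prof$samples$psi[k] + mVs(1)
  rep <- validate_profile(prof, inp, check_convergence = FALSE)
  row <- rep$table[rep$table$check == "sample smoothness", ]
  expect_false(row$pass)
  expect_match(row$note, "discontinuity near x")
})

test_that("bilayer segment is linear to machine precision", {
  inp <- load_preset("neuroblastoma", "resting")
  sol <- solve_surface_potentials(inp)
  prof <- assemble_profile(inp, sol, n_steps = 400)
  b <- prof$samples[prof$samples$region == "b", ]
  chord <- b$psi[1] + (b$psi[nrow(b)] - b$psi[1]) *
    (b$x - b$x[1]) / (b$x[nrow(b)] - b$x[1])
  expect_lt(max(abs(b$psi - chord)) / max(abs(b$psi)), 1e-12)
})

test_that("profile CSV writer emits the documented format", {
  inp <- load_preset("ganglion", "action")
  sol <- solve_surface_potentials(inp)
  prof <- assemble_profile(inp, sol, n_steps = 200)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, tmp)
  got <- utils::read.csv(tmp)
  expect_identical(names(got), c("x_nm", "psi_mV", "region"))
  expect_identical(nrow(got), nrow(prof$samples))
  meta <- jsonlite::fromJSON(paste0(tmp, ".json"))
  expect_identical(meta$state, "action")
  expect_true(is.numeric(meta$psi3_mV))
})
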