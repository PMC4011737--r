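test_that("Helmholtz-Smoluchowski psi1 is linear in the mobility", {
  kin0 <- list(electrophoretic_mobility = 0, viscosity_eta = 1)
  expect_identical(psi1_from_mobility(kin0, 81), 0)
  kin1 <- list(electrophoretic_mobility = -2e-4, viscosity_eta = 1)
  kin2 <- list(electrophoretic_mobility = -4e-4, viscosity_eta = 1)
  expect_equal(psi1_from_mobility(kin2, 81), 2 * psi1_from_mobility(kin1, 81))
  expect_error(psi1_from_mobility(list(electrophoretic_mobility = 1,
                                       viscosity_eta = 0), 81), "viscosity")
  # direct evaluation: zeta = 4 pi eta mu / eps
  expect_rel_equal(psi1_from_mobility(kin1, 81),
                   4 * pi * 1 * -2e-4 / 81, tol = 1e-14)
})

test_that("check_jump reduces to field continuity and matches Gauss' law", {
  cont <- list(surface = "S1", sigma = 0, eps_left = 81, eps_right = 81,
               field_left = 123.4, field_right = 120.1)
  expect_equal(check_jump(cont), 123.4 - 120.1)
  set.seed(11)
  for (i in 1:20) {
    cond <- list(surface = "S2", sigma = runif(1, -5000, 0),
                 eps_left = runif(1, 2, 100), eps_right = runif(1, 2, 100),
                 field_left = runif(1, -1000, 1000),
                 field_right = runif(1, -1000, 1000))
    direct <- (cond$eps_left * cond$field_left + 4 * pi * cond$sigma -
                 cond$eps_right * cond$field_right) /
      max(cond$eps_left, cond$eps_right)
    expect_equal(check_jump(cond), direct)
  }
})

test_that("the charge-free symmetric toy has the flat zero solution", {
  toy <- toy_symmetric()
  expect_identical(as.numeric(surface_map_G(0, toy)), 0)
  expect_identical(as.numeric(surface_map_F(0, toy)), 0)
  sol <- solve_surface_potentials(toy)
  expect_identical(sol$psi1, 0)
  expect_equal(sol$psi2, 0)
  expect_equal(sol$psi3, 0)
})

test_that("F and G are self-consistent at a solved preset state", {
  inp <- load_preset("ganglion", "resting")
  sol <- solve_surface_potentials(inp)
  p2 <- as.numeric(surface_map_G(sol$psi3, inp, prev = sol$psi2))
  p3 <- as.numeric(surface_map_F(sol$psi2, inp, prev = sol$psi3))
  expect_lt(smV(abs(p2 - sol$psi2)), 1e-6)
  expect_lt(smV(abs(p3 - sol$psi3)), 1e-6)
  # composition order does not change the fixed point
  h1 <- as.numeric(surface_map_F(p2, inp, prev = sol$psi3))
  g1 <- as.numeric(surface_map_G(h1, inp, prev = sol$psi2))
  expect_lt(smV(abs(g1 - sol$psi2)), 1e-4)
})

test_that("maps agree with a brute-force 1-D residual scan on a toy", {
  toy <- toy_charged()
  psi3_fix <- mVs(-70)
  got <- as.numeric(surface_map_G(psi3_fix, toy))
  # independent dense scan of the squared-jump residual at 1e-6 mV
  cs <- membranepb:::.coef_set(toy)
  Eg1 <- membranepb:::.field_g_S1(toy, cs$e)
  f <- function(p2) {
    Em <- (p2 - psi3_fix) / toy$geometry$hb
    81^2 * membranepb:::.field_g_sq(p2, toy, cs, Eg1) -
      (2 * Em - 4 * pi * toy$charges$sigma2)^2
  }
  grid <- mVs(seq(-10, 0, by = 1e-4))
  v <- f(grid)
  i <- which(v[-length(v)] * v[-1] < 0)[1]
  # refine to 1e-6 mV by bisection on the bracket
  lo <- grid[i]; hi <- grid[i + 1]
  for (k in 1:20) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_lt(smV(abs(got - (lo + hi) / 2)), 1e-3)
})

test_that("solver contract: residuals, ordering, and jump closure", {
  for (cell in c("ganglion", "neuroblastoma")) {
    inp <- load_preset(cell, "resting")
    sol <- solve_surface_potentials(inp)
    expect_lt(smV(sol$residual_F), 1e-4)
    # resting surface potentials are negative for these cells
    expect_lt(sol$psi1, 0)
    expect_lt(sol$psi2, 0)
    expect_lt(sol$psi3, 0)
    fields <- membranepb:::.surface_fields(inp, sol$psi2, sol$psi3)
    scale <- max(abs(unlist(fields)), 1)
    expect_lt(max(abs(sol$jump_residuals)) / scale, 1e-8)
  }
})

test_that("fixed point and bracketed fallback find the same root", {
  for (cell in c("ganglion", "neuroblastoma")) {
    inp <- load_preset(cell, "resting")
    a <- solve_surface_potentials(inp, method = "fixed_point")
    b <- solve_surface_potentials(inp, method = "bracketed_fallback")
    expect_lt(smV(abs(a$psi3 - b$psi3)), 1e-3)
    expect_lt(smV(abs(a$psi2 - b$psi2)), 1e-3)
  }
})

test_that("an empty scan window reports no root", {
  toy <- toy_charged()
  expect_error(surface_map_F(mVs(-3), toy, window = mVs(c(-200, -150))),
               "no root in window")
})
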