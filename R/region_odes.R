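# First-integral ordinary differential equations for the three aqueous
# regions and the linear bilayer solution.
#
# In each aqueous region the Poisson-Boltzmann equation admits the first
# integral (dpsi/dx)^2 = .pb_energy(psi) + K, where K is fixed by one
# boundary condition: zero slope in the bulk (extracellular, cytoplasm)
# or a known interface field (glycocalyx).

#' First-integral constant for the extracellular region
#'
#' Chosen so that the slope vanishes where the potential reaches its
#' extracellular bulk value (0 by convention).  The extracellular fixed
#' charge density is zero.
#'
#' @param coeffs [region_coefficients()] for the extracellular region.
#' @param psi_inf bulk extracellular potential, statV (0 by convention).
#' @param constants a [physical_constants()] object.
#' @return list of class `first_integral_constant`.
#' @export
extracellular_constant <- function(coeffs, psi_inf = 0,
                                   constants = physical_constants()) {
  if (coeffs$alpha == 0 && coeffs$beta == 0) {
    stop("degenerate electrolyte: alpha and beta both zero is unphysical")
  }
  K <- -.pb_energy(psi_inf, coeffs, constants)
  structure(list(K = K, region = "e", zero_slope_at = psi_inf),
            class = "first_integral_constant")
}

#' First-integral constant for the cytoplasmic region
#'
#' Chosen so that the slope vanishes at the bulk cytoplasmic potential
#' (the transmembrane potential).  Includes the cytoplasmic fixed-charge
#' contribution.
#'
#' @param coeffs [region_coefficients()] for the cytoplasm.
#' @param psi_cyt_bulk bulk cytoplasmic potential, statV.
#' @inheritParams extracellular_constant
#' @export
cytoplasm_constant <- function(coeffs, psi_cyt_bulk,
                               constants = physical_constants()) {
  stopifnot(is.finite(psi_cyt_bulk))
  K <- -.pb_energy(psi_cyt_bulk, coeffs, constants)
  structure(list(K = K, region = "c", zero_slope_at = psi_cyt_bulk),
            class = "first_integral_constant")
}

#' First-integral constant for the glycocalyx region
#'
#' The glycocalyx has no interior bulk, so its constant is anchored at a
#' surface where both the potential and the glycocalyx-side field are
#' known (either S1, via the Gauss jump from the extracellular side, or
#' S2, via the jump from the bilayer field).
#'
#' @param psi_anchor potential at the anchoring surface, statV.
#' @param field_anchor glycocalyx-side electric field E = -dpsi/dx at the
#'   anchoring surface, statV/cm.
#' @param coeffs [region_coefficients()] for the glycocalyx.
#' @inheritParams extracellular_constant
#' @export
glycocalyx_constant <- function(psi_anchor, field_anchor, coeffs,
                                constants = physical_constants()) {
  K <- field_anchor^2 - .pb_energy(psi_anchor, coeffs, constants)
  structure(list(K = K, region = "g", zero_slope_at = NA_real_,
                 anchor = c(psi = psi_anchor, field = field_anchor)),
            class = "first_integral_constant")
}

#' Regional first-integral ODE
#'
#' Bundles coefficients, first-integral constant, square-root branch sign
#' and the anchoring boundary point into an integrable object.
#'
#' @param region `"e"`, `"g"` or `"c"`.
#' @param coeffs [region_coefficients()].
#' @param constant matching `first_integral_constant`.
#' @param slope_sign +1 or -1; fixed branch of dpsi/dx = sign * sqrt(...).
#' @param boundary_point list `(x =, psi =)`, the anchoring sample.
#' @param constants a [physical_constants()] object.
#' @export
region_ode <- function(region, coeffs, constant, slope_sign, boundary_point,
                       constants = physical_constants()) {
  stopifnot(region %in% c("e", "g", "c"), slope_sign %in% c(-1, 1),
            constant$region == region)
  structure(list(region = region, coeffs = coeffs, constant = constant,
                 slope_sign = slope_sign, boundary_point = boundary_point,
                 constants = constants),
            class = "region_ode")
}

# square of the slope (first-integral expression), vectorized
.slope_sq <- function(ode, psi) {
  .pb_energy(psi, ode$coeffs, ode$constants) + ode$constant$K
}

#' Slope of the potential from the first integral
#'
#' dpsi/dx = slope_sign * sqrt(first-integral expression).  Arguments of
#' the square root within -1e-12 of the local energy scale are clamped to
#' zero (turning-point tolerance); substantially negative arguments mean
#' the requested potential is not reachable on the anchored branch.
#'
#' @param ode a [region_ode()].
#' @param psi potential(s), statV.
#' @return dpsi/dx, statV/cm.
#' @export
slope <- function(ode, psi) {
  s2 <- .slope_sq(ode, psi)
  scale <- .pb_energy_scale(psi, ode$coeffs, ode$constants) + abs(ode$constant$K)
  bad <- s2 < -1e-12 * scale
  if (any(bad)) {
    stop(sprintf(
      "potential outside reachable branch (region %s, psi = %.6g mV, deficit %.3g)",
      ode$region, .statV_to_mV(psi[which(bad)[1]]), min(s2[bad])))
  }
  s2[s2 < 0] <- 0
  ode$slope_sign * sqrt(s2)
}

#' Linear potential across the charge-free bilayer
#'
#' The hydrophobic bilayer carries no volume charge, so the potential is
#' the chord between (x_S2, psi2) and (x_S3, psi3); the implied field
#' E_m = -(psi3 - psi2)/hb is constant.
#'
#' @param psi2,psi3 surface potentials on S2 and S3, statV.
#' @param geometry geometry list from [model_inputs()].
#' @param x position(s) in cm, within [x_S2, x_S3].
#' @return potential(s), statV.
#' @export
bilayer_profile <- function(psi2, psi3, geometry, x) {
  tol <- 1e-9 * max(geometry$hb, 1e-30)
  if (any(x < geometry$x_S2 - tol | x > geometry$x_S3 + tol)) {
    stop("x outside the bilayer [x_S2, x_S3]")
  }
  t <- (x - geometry$x_S2) / geometry$hb
  psi2 * (1 - t) + psi3 * t   # exact at both endpoints
}
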