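# Boltzmann ion statistics, volumetric charge densities and the ionic
# coefficients entering the Poisson-Boltzmann first integral, plus two
# closed-form diffuse double-layer oracles (Debye length, Gouy-Chapman)
# kept internal and used only for validation.

#' Describe one mobile ion species
#'
#' @param valence_z signed valence, one of -2, -1, +1, +2 (the model
#'   truncates the electrolyte to mono- and divalent ions).
#' @param boundary_conc reference molar density, mol/cm^3.
#' @param region region the species lives in: `"e"`, `"g"` or `"c"`.
#' @return list of class `ion_species`.
#' @export
ion_species <- function(valence_z, boundary_conc, region = "e") {
  if (!valence_z %in% c(-2L, -1L, 1L, 2L)) {
    stop("valence must be one of -2, -1, +1, +2")
  }
  stopifnot(boundary_conc >= 0, region %in% c("e", "g", "c"))
  structure(list(valence_z = as.integer(valence_z),
                 boundary_conc = boundary_conc, region = region),
            class = "ion_species")
}

#' Boltzmann-distributed ionic concentration
#'
#' Concentration of a mobile species at local potential `psi`, relative to
#' its reference pair (`psi_bound`, boundary concentration):
#' C = C_bound * exp(-z q (psi - psi_bound) / kT).
#'
#' @param species an [ion_species()].
#' @param psi local electric potential, statV (may be a vector).
#' @param psi_bound reference potential, statV.
#' @param constants a [physical_constants()] object.
#' @return concentration(s), mol/cm^3.
#' @export
boltzmann_concentration <- function(species, psi, psi_bound,
                                    constants = physical_constants()) {
  stopifnot(all(is.finite(psi)))
  u <- (psi - psi_bound) / .thermal_voltage(constants)
  species$boundary_conc * exp(-species$valence_z * u)
}

#' Volumetric charge density of a set of ion concentrations
#'
#' Sum of z_i * q * N_A * C_i over the supplied species.  Avogadro scaling
#' from molar density to particle density is applied here so that the
#' result closes in statC/cm^3.
#'
#' @param concs data.frame with columns `valence_z` and `conc`
#'   (mol/cm^3), one row per species.
#' @param constants a [physical_constants()] object.
#' @return charge density, statC/cm^3.
#' @export
volumetric_charge_density <- function(concs,
                                      constants = physical_constants()) {
  stopifnot(nrow(concs) > 0, all(c("valence_z", "conc") %in% names(concs)))
  q <- constants$electron_charge_q
  sum(concs$valence_z * q * .AVOGADRO * concs$conc)
}

#' Ionic coefficients of the Poisson-Boltzmann first integral
#'
#' For a symmetric electrolyte truncated to mono- and divalent pairs, the
#' first integral of the Poisson-Boltzmann equation in region j reads
#'
#'   (dpsi/dx)^2 = (8 pi / eps_j) (alpha_j cosh u + beta_j cosh 2u
#'                                  - rho_fj psi) + K_j,
#'
#' with u = q (psi - psi_bound_j)/kT.  `alpha_j = 2 N_A k T C1_j` and
#' `beta_j = 2 N_A k T C2_j` carry the influence of the boundary mono- and
#' divalent concentrations (erg/cm^3); the fixed-charge density enters
#' linearly.  The extracellular fixed term is forced to zero.
#'
#' @param ions one region entry of `model_inputs$ions`: a list with
#'   `mono`, `div` (mol/cm^3) and `psi_bound` (statV).
#' @param rho_f fixed volumetric charge density in the region, statC/cm^3.
#' @param dielectric relative permittivity of the region.
#' @param constants a [physical_constants()] object.
#' @param region `"e"`, `"g"` or `"c"`.
#' @return list of class `region_coefficients` with `alpha`, `beta`,
#'   `fixed_term`, `psi_bound`, `dielectric`, `region`.
#' @export
region_coefficients <- function(ions, rho_f, dielectric,
                                constants = physical_constants(),
                                region = "e") {
  stopifnot(region %in% c("e", "g", "c"))
  if (dielectric <= 0) stop("dielectric constant must be positive")
  kT <- constants$boltzmann_k * constants$temperature_T
  structure(list(
    alpha = 2 * .AVOGADRO * kT * ions$mono,
    beta = 2 * .AVOGADRO * kT * ions$div,
    fixed_term = if (region == "e") 0 else rho_f,
    psi_bound = ions$psi_bound,
    dielectric = dielectric,
    region = region
  ), class = "region_coefficients")
}

# "energy" part of the first integral: (8 pi / eps) *
#   (alpha cosh u + beta cosh 2u - rho_f * psi); vectorized in psi
.pb_energy <- function(psi, coeffs, constants) {
  u <- (psi - coeffs$psi_bound) / .thermal_voltage(constants)
  (8 * pi / coeffs$dielectric) *
    (coeffs$alpha * cosh(u) + coeffs$beta * cosh(2 * u) -
       coeffs$fixed_term * psi)
}

# magnitude scale of the energy terms, for relative clamping of the
# square-root argument near turning points
.pb_energy_scale <- function(psi, coeffs, constants) {
  u <- (psi - coeffs$psi_bound) / .thermal_voltage(constants)
  (8 * pi / coeffs$dielectric) *
    (coeffs$alpha * cosh(u) + coeffs$beta * cosh(2 * u) +
       abs(coeffs$fixed_term * psi))
}

# Debye screening length (classical closed form), used as an independent
# validation oracle.  Ionic strength I = C1 + 4 C2 for the symmetric
# mono+divalent electrolyte.
debye_length <- function(ions, dielectric, constants = physical_constants()) {
  ionic_strength <- ions$mono + 4 * ions$div
  if (ionic_strength <= 0) stop("zero ionic strength")
  kT <- constants$boltzmann_k * constants$temperature_T
  q <- constants$electron_charge_q
  sqrt(dielectric * kT / (8 * pi * q^2 * .AVOGADRO * ionic_strength))
}

# Closed-form nonlinear Gouy-Chapman profile for a symmetric 1:1
# electrolyte with no fixed charges; validation oracle only.
# psi(x) = (4kT/q) artanh( tanh(q psi0 / 4kT) * exp(-kappa x) )
gouy_chapman_profile <- function(psi0, mono_conc, dielectric, constants,
                                 x_grid, div_conc = 0) {
  if (div_conc > 0) stop("Gouy-Chapman oracle requires a monovalent-only electrolyte")
  kT <- constants$boltzmann_k * constants$temperature_T
  q <- constants$electron_charge_q
  kappa <- 1 / debye_length(list(mono = mono_conc, div = 0), dielectric,
                            constants)
  gamma <- tanh(q * psi0 / (4 * kT))
  psi <- (4 * kT / q) * atanh(gamma * exp(-kappa * x_grid))
  data.frame(x = x_grid, psi = psi)
}
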