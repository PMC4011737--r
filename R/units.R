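# Internal unit system is Gaussian CGS: cm, erg, statV, statC, poise.
# SI values are accepted/emitted only through convert_units() and the
# preset files' unit-suffixed keys.

.AVOGADRO <- 6.02214076e23          # mol^-1
.STATV_PER_V <- 1 / 299.792458      # 1 V expressed in statV
.STATV_PER_MV <- 1e-3 / 299.792458
.STATC_PER_C <- 2.99792458e9

#' Physical constants in CGS units
#'
#' Bundles Boltzmann's constant, the absolute value of the electron charge
#' and the absolute temperature used throughout the electrostatic model.
#'
#' @param boltzmann_k Boltzmann's constant in erg/K.
#' @param electron_charge_q absolute electron charge in statC.
#' @param temperature_T absolute temperature in K.
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(boltzmann_k = 1.380649e-16,
                               electron_charge_q = 4.80320425e-10,
                               temperature_T = 310) {
  stopifnot(boltzmann_k > 0, electron_charge_q > 0, temperature_T > 0)
  structure(list(boltzmann_k = boltzmann_k,
                 electron_charge_q = electron_charge_q,
                 temperature_T = temperature_T),
            class = "physical_constants")
}

# thermal voltage kT/q in statV
.thermal_voltage <- function(constants) {
  constants$boltzmann_k * constants$temperature_T / constants$electron_charge_q
}

# CGS units per one SI unit, by supported dimension
.UNIT_FACTORS <- c(
  length                 = 100,             # m -> cm
  concentration          = 1e-3,            # mol/L -> mol/cm^3
  potential              = 1 / 299.792458,  # V -> statV
  charge                 = 2.99792458e9,    # C -> statC
  surface_charge_density = 2.99792458e5,    # C/m^2 -> statC/cm^2
  volume_charge_density  = 2.99792458e3,    # C/m^3 -> statC/cm^3
  viscosity              = 10,              # Pa s -> poise
  mobility               = 2.99792458e6,    # m^2/(V s) -> cm^2/(statV s)
  energy                 = 1e7,             # J -> erg
  temperature            = 1               # K -> K
)

#' Convert a physical quantity between SI and CGS
#'
#' Supports the dimensions appearing in the model's parameter tables.
#' Conversions are exact rational multiples of the defined speed of light,
#' so round trips are identities to floating-point precision.
#'
#' @param value numeric quantity.
#' @param dimension one of `r paste0('"', names(.UNIT_FACTORS), '"', collapse = ", ")`.
#' @param from,to source and target unit system, `"SI"` or `"CGS"`.
#' @return converted numeric value.
#' @examples
#' convert_units(2.5e-9, "length", from = "SI", to = "CGS")   # 2.5 nm -> cm
#' convert_units(0.154, "concentration", from = "SI", to = "CGS")
#' convert_units(0.1, "viscosity", from = "SI", to = "CGS")   # Pa s -> poise
#' @export
convert_units <- function(value, dimension, from = c("SI", "CGS"),
                          to = c("CGS", "SI")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (!dimension %in% names(.UNIT_FACTORS)) {
    stop("unsupported dimension: ", dimension)
  }
  if (from == to) return(value)
  f <- .UNIT_FACTORS[[dimension]]
  if (from == "SI") value * f else value / f
}

# convenience: millivolt <-> statV (internal)
.mV_to_statV <- function(mv) mv * .STATV_PER_MV
.statV_to_mV <- function(sv) sv / .STATV_PER_MV
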