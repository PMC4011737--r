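# Model parameterization: geometry, dielectrics, ionic boundary values,
# fixed charges, electrokinetics and membrane state, assembled into a
# `model_inputs` object.  All fields are stored in CGS units.

#' Assemble a complete model parameterization
#'
#' Low-level constructor for the full physical description of one cell in
#' one membrane state.  Positions follow the convention that x increases
#' from the extracellular bath toward the cytoplasm, with the outer
#' glycocalyx surface S1 at x = 0, S2 at x = hg and S3 at x = hg + hb.
#'
#' Ionic boundary values are reference pairs (concentration, potential):
#' the extracellular pair is taken in the bulk bath (potential 0 by
#' convention), the glycocalyx pair on S1 (potential psi1, filled in from
#' the electrophoretic mobility when `psi1` is `NULL`), and the
#' cytoplasmic pair in the bulk cytoplasm (potential = the transmembrane
#' potential).
#'
#' @param cell_name label for the parameter set.
#' @param state `"resting"` or `"action"`.
#' @param transmembrane_potential bulk cytoplasm minus bulk extracellular
#'   potential, statV (negative at rest).
#' @param hg,hb glycocalyx width and bilayer thickness, cm.
#' @param eps_e,eps_g,eps_b,eps_c relative permittivities of the
#'   extracellular, glycocalyx, bilayer and cytoplasmic regions.
#' @param mono_e,div_e monovalent/divalent boundary concentrations for the
#'   extracellular bulk, mol/cm^3.
#' @param mono_g,div_g boundary concentrations on S1 (glycocalyx
#'   reference), mol/cm^3.
#' @param mono_c,div_c bulk cytoplasmic boundary concentrations, mol/cm^3.
#' @param rho_f_g,rho_f_c fixed volumetric charge densities in glycocalyx
#'   and cytoplasm, statC/cm^3 (the extracellular fixed density is
#'   identically zero).
#' @param sigma1,sigma2,sigma3 surface charge densities on S1, S2, S3,
#'   statC/cm^2.
#' @param mobility electrophoretic mobility, cm^2/(statV s).
#' @param viscosity viscosity entering the Helmholtz-Smoluchowski
#'   relation, poise.
#' @param psi1 potential on S1 in statV, or `NULL` to derive it from the
#'   mobility.
#' @param constants a [physical_constants()] object.
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(cell_name = "custom",
                         state = c("resting", "action"),
                         transmembrane_potential = .mV_to_statV(-70),
                         hg = 2.5e-7, hb = 7.5e-7,
                         eps_e = 81, eps_g = 81, eps_b = 2, eps_c = 81,
                         mono_e = 1.54e-4, div_e = 2e-6,
                         mono_g = 1.54e-4, div_g = 2e-6,
                         mono_c = 1.54e-4, div_c = 4e-7,
                         rho_f_g = 0, rho_f_c = 0,
                         sigma1 = 0, sigma2 = 0, sigma3 = 0,
                         mobility = 0, viscosity = 1,
                         psi1 = NULL,
                         constants = physical_constants()) {
  state <- match.arg(state)
  geometry <- list(hg = hg, hb = hb,
                   x_S1 = 0, x_S2 = hg, x_S3 = hg + hb)
  kinetics <- list(electrophoretic_mobility = mobility,
                   viscosity_eta = viscosity,
                   zeta_potential = NA_real_)
  inputs <- structure(list(
    cell_name = cell_name,
    constants = constants,
    geometry = geometry,
    dielectrics = list(e = eps_e, g = eps_g, b = eps_b, c = eps_c),
    ions = list(
      e = list(mono = mono_e, div = div_e, psi_bound = 0),
      g = list(mono = mono_g, div = div_g, psi_bound = NA_real_),
      c = list(mono = mono_c, div = div_c,
               psi_bound = transmembrane_potential)
    ),
    charges = list(rho_f_g = rho_f_g, rho_f_c = rho_f_c,
                   sigma1 = sigma1, sigma2 = sigma2, sigma3 = sigma3),
    kinetics = kinetics,
    state = list(label = state,
                 transmembrane_potential = transmembrane_potential)
  ), class = "model_inputs")
  if (is.null(psi1)) {
    psi1 <- psi1_from_mobility(kinetics, eps_e, psi_extracellular_bulk = 0)
  }
  inputs$kinetics$zeta_potential <- psi1
  inputs$ions$g$psi_bound <- psi1
  inputs
}

.PRESET_CELLS <- c("ganglion", "neuroblastoma")
.PRESET_STATES <- c("resting", "action")

# keys a preset file must define, with the dimension implied by the suffix
.PRESET_SCHEMA <- c(
  "eps_extracellular", "eps_glycocalyx", "eps_bilayer", "eps_cytoplasm",
  "glycocalyx_width_hg_cm", "bilayer_thickness_hb_cm",
  "mono_conc_extracellular_mol_cm3", "div_conc_extracellular_mol_cm3",
  "mono_conc_S1_mol_cm3", "div_conc_S1_mol_cm3",
  "mono_conc_cytoplasm_mol_cm3", "div_conc_cytoplasm_mol_cm3",
  "temperature_K", "boltzmann_k_erg_K", "electron_charge_statC",
  "viscosity_poise",
  "rho_f_glycocalyx_statC_cm3", "rho_f_cytoplasm_statC_cm3",
  "sigma_S1_statC_cm2", "sigma_S2_statC_cm2", "sigma_S3_statC_cm2",
  "electrophoretic_mobility_cm2_statV_s",
  "transmembrane_potential_mV"
)

# parse "key = value  # note" lines
.read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(\\S+)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  out <- as.list(vals)
  names(out) <- keys
  out
}

#' Load a built-in cell preset
#'
#' Reads the plain-text parameter file for one cell in one membrane state
#' and returns a fully populated [model_inputs()] object in CGS units.
#' The shared physical parameters (geometry, dielectrics, bulk ionic
#' concentrations, temperature, viscosity) are literature values; the
#' cell-specific charge densities and mobilities are a synthetic
#' reconstruction chosen to reproduce the qualitative electrostatic
#' behavior of each cell type (see the package vignette).
#'
#' @param cell_name `"ganglion"` (healthy spinal ganglion neuron) or
#'   `"neuroblastoma"` (tumorous cell).
#' @param state_label `"resting"` or `"action"`.
#' @param overrides optional named list (or path to a config file) whose
#'   entries replace preset keys before assembly.
#' @return A [model_inputs()] object.
#' @examples
#' inp <- load_preset("ganglion", "resting")
#' inp$constants$temperature_T     # 310 K
#' @export
load_preset <- function(cell_name, state_label, overrides = NULL) {
  if (!cell_name %in% .PRESET_CELLS) {
    stop("unknown preset: ", cell_name,
         " (available: ", paste(.PRESET_CELLS, collapse = ", "), ")")
  }
  if (!state_label %in% .PRESET_STATES) {
    stop("unknown state: ", state_label,
         " (available: ", paste(.PRESET_STATES, collapse = ", "), ")")
  }
  fname <- sprintf("%s_%s_synthetic.cfg", cell_name, state_label)
  path <- system.file("extdata", "presets", fname, package = "membranepb")
  if (!nzchar(path)) stop("preset file not found: ", fname)
  cfg <- .read_config(path)
  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L) {
      overrides <- .read_config(overrides)
    }
    cfg[names(overrides)] <- lapply(overrides, as.character)
  }
  missing <- setdiff(.PRESET_SCHEMA, names(cfg))
  if (length(missing)) {
    stop("preset ", fname, " is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(v)) stop("non-numeric value for ", key)
    v
  }
  constants <- physical_constants(
    boltzmann_k = num("boltzmann_k_erg_K"),
    electron_charge_q = num("electron_charge_statC"),
    temperature_T = num("temperature_K"))
  model_inputs(
    cell_name = cell_name,
    state = state_label,
    transmembrane_potential = .mV_to_statV(num("transmembrane_potential_mV")),
    hg = num("glycocalyx_width_hg_cm"),
    hb = num("bilayer_thickness_hb_cm"),
    eps_e = num("eps_extracellular"), eps_g = num("eps_glycocalyx"),
    eps_b = num("eps_bilayer"), eps_c = num("eps_cytoplasm"),
    mono_e = num("mono_conc_extracellular_mol_cm3"),
    div_e = num("div_conc_extracellular_mol_cm3"),
    mono_g = num("mono_conc_S1_mol_cm3"),
    div_g = num("div_conc_S1_mol_cm3"),
    mono_c = num("mono_conc_cytoplasm_mol_cm3"),
    div_c = num("div_conc_cytoplasm_mol_cm3"),
    rho_f_g = num("rho_f_glycocalyx_statC_cm3"),
    rho_f_c = num("rho_f_cytoplasm_statC_cm3"),
    sigma1 = num("sigma_S1_statC_cm2"),
    sigma2 = num("sigma_S2_statC_cm2"),
    sigma3 = num("sigma_S3_statC_cm2"),
    mobility = num("electrophoretic_mobility_cm2_statV_s"),
    viscosity = num("viscosity_poise"),
    constants = constants)
}

#' Validate a model parameterization
#'
#' Runs all type invariants over a [model_inputs()] object and returns a
#' machine-readable report; failures are recorded, not raised.
#'
#' @param inputs a [model_inputs()] object.
#' @return A `validation_report` with one row per check.
#' @export
validate_inputs <- function(inputs) {
  rows <- list()
  add <- function(check, pass, note = "", severity = "error",
                  residual = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, pass = pass, severity = severity,
      residual = residual, note = note, stringsAsFactors = FALSE)
  }
  cst <- inputs$constants
  add("constants positive",
      cst$boltzmann_k > 0 && cst$electron_charge_q > 0 && cst$temperature_T > 0)
  geo <- inputs$geometry
  add("glycocalyx width positive", geo$hg > 0,
      if (geo$hg <= 0) "glycocalyx width must be positive" else "")
  add("bilayer thickness positive", geo$hb > 0,
      if (geo$hb <= 0) "bilayer thickness must be positive" else "")
  add("interface spacing consistent",
      isTRUE(all.equal(geo$x_S2 - geo$x_S1, geo$hg)) &&
        isTRUE(all.equal(geo$x_S3 - geo$x_S2, geo$hb)),
      residual = abs((geo$x_S2 - geo$x_S1) - geo$hg) +
        abs((geo$x_S3 - geo$x_S2) - geo$hb))
  eps <- unlist(inputs$dielectrics)
  add("dielectric constants >= 1", all(eps >= 1))
  conc <- c(inputs$ions$e$mono, inputs$ions$e$div,
            inputs$ions$g$mono, inputs$ions$g$div,
            inputs$ions$c$mono, inputs$ions$c$div)
  add("boundary concentrations positive", all(conc[c(1, 3, 5)] > 0) &&
        all(conc[c(2, 4, 6)] >= 0))
  ch <- inputs$charges
  add("fixed charge densities non-positive",
      ch$rho_f_g <= 0 && ch$rho_f_c <= 0,
      if (ch$rho_f_g > 0 || ch$rho_f_c > 0)
        "sign contradicts negatively charged glycocalyx/cytoplasm" else "",
      severity = "warning")
  add("inner surface charges non-positive",
      ch$sigma2 <= 0 && ch$sigma3 <= 0,
      if (ch$sigma3 > 0 || ch$sigma2 > 0)
        "sign contradicts negatively charged inner surfaces" else "",
      severity = "warning")
  add("viscosity positive", inputs$kinetics$viscosity_eta > 0)
  st <- inputs$state
  if (st$label == "resting") {
    add("resting transmembrane potential negative",
        st$transmembrane_potential < 0, severity = "warning")
  }
  add("glycocalyx reference potential set",
      is.finite(inputs$ions$g$psi_bound))
  structure(list(table = do.call(rbind, rows), subject = inputs$cell_name),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  tab <- x$table
  cat("Validation report (", x$subject, "): ",
      sum(tab$pass), "/", nrow(tab), " checks passed\n", sep = "")
  for (i in seq_len(nrow(tab))) {
    mark <- if (tab$pass[i]) "ok  " else
      if (tab$severity[i] == "warning") "WARN" else "FAIL"
    cat(sprintf("  [%s] %s", mark, tab$check[i]))
    if (!tab$pass[i] && nzchar(tab$note[i])) cat(" -- ", tab$note[i])
    cat("\n")
  }
  invisible(x)
}

#' @export
print.model_inputs <- function(x, ...) {
  cat("Membrane model inputs:", x$cell_name, "/", x$state$label, "\n")
  cat(sprintf("  transmembrane potential: %.2f mV\n",
              .statV_to_mV(x$state$transmembrane_potential)))
  cat(sprintf("  psi1 (from mobility):    %.2f mV\n",
              .statV_to_mV(x$ions$g$psi_bound)))
  cat(sprintf("  geometry: hg = %.3g nm, hb = %.3g nm\n",
              x$geometry$hg * 1e7, x$geometry$hb * 1e7))
  cat(sprintf("  charges: rho_fg = %.3g, rho_fc = %.3g statC/cm^3; sigma = (%.3g, %.3g, %.3g) statC/cm^2\n",
              x$charges$rho_f_g, x$charges$rho_f_c,
              x$charges$sigma1, x$charges$sigma2, x$charges$sigma3))
  invisible(x)
}
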