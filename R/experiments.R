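# Computational experiments: charge-ratio sensitivity sweeps of the
# surface potentials and full resting/AP profiles for both cell presets.

#' Specify a charge-ratio sensitivity sweep
#'
#' A grid value r rescales the preset base charge to r * base (base
#' values are negative, so r > 1 means more negative charge), leaving all
#' other charges at their preset values.
#'
#' @param swept_quantity `"sigma_S2_ratio"` (inner-leaflet surface charge
#'   on S2) or `"rho_fc_ratio"` (cytoplasmic fixed charge density).
#' @param ratio_grid non-empty vector of multipliers with |r| >= 1;
#'   default 32 log-spaced points over 1..10.
#' @param cells subset of the available presets.
#' @param states subset of `c("resting", "action")`.
#' @return list of class `sweep_spec`.
#' @export
sweep_spec <- function(swept_quantity = c("sigma_S2_ratio", "rho_fc_ratio"),
                       ratio_grid = 10^seq(0, 1, length.out = 32),
                       cells = c("ganglion", "neuroblastoma"),
                       states = c("resting", "action")) {
  swept_quantity <- match.arg(swept_quantity)
  if (length(ratio_grid) == 0) stop("empty ratio grid")
  if (any(abs(ratio_grid) < 1)) {
    stop("ratio multipliers must have magnitude >= 1 (scaling toward more negative charge)")
  }
  stopifnot(all(cells %in% .PRESET_CELLS), all(states %in% .PRESET_STATES))
  structure(list(swept_quantity = swept_quantity, ratio_grid = ratio_grid,
                 cells = cells, states = states),
            class = "sweep_spec")
}

# apply a ratio to the swept charge of a model_inputs object
.apply_ratio <- function(inputs, quantity, r) {
  if (quantity == "sigma_S2_ratio") {
    inputs$charges$sigma2 <- r * inputs$charges$sigma2
  } else {
    inputs$charges$rho_f_c <- r * inputs$charges$rho_f_c
  }
  inputs
}

#' Run a charge-ratio sensitivity sweep
#'
#' For each grid point, cell and state, rebuilds the model inputs with
#' the scaled charge, re-solves the surface-potential system and records
#' the outcome.  Non-convergent points are flagged, not fatal.
#'
#' @param spec a [sweep_spec()].
#' @param method solver method passed to [solve_surface_potentials()].
#' @return data.frame of class `sweep_result` with one row per
#'   (cell, state, ratio).
#' @export
run_sweep <- function(spec, method = "fixed_point") {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (cell in spec$cells) {
    for (state in spec$states) {
      base <- load_preset(cell, state)
      for (r in spec$ratio_grid) {
        inputs <- .apply_ratio(base, spec$swept_quantity, r)
        sol <- tryCatch(solve_surface_potentials(inputs, method = method),
                        error = function(e) e)
        if (inherits(sol, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            cell = cell, state = state, ratio = r,
            psi1_mV = NA_real_, psi2_mV = NA_real_, psi3_mV = NA_real_,
            residual_mV = NA_real_, iterations = NA_integer_,
            converged = FALSE, note = conditionMessage(sol),
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            cell = cell, state = state, ratio = r,
            psi1_mV = .statV_to_mV(sol$psi1),
            psi2_mV = .statV_to_mV(sol$psi2),
            psi3_mV = .statV_to_mV(sol$psi3),
            residual_mV = .statV_to_mV(sol$residual_F),
            iterations = sol$iterations,
            converged = TRUE, note = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", class(out))
  out
}

#' Compute validated potential profiles for cell presets
#'
#' Solves the surface system and assembles the full profile for each
#' requested (cell, state) pair; attaches a comparison summary including
#' the potential drop across the glycocalyx, delta_psi_glyco = psi2 - psi1.
#'
#' @param cells,states preset subsets as in [sweep_spec()].
#' @param n_steps RK4 steps per region.
#' @param method solver method.
#' @return named list of `potential_profile` objects with a `summary`
#'   data.frame attribute.
#' @export
run_profiles <- function(cells = c("ganglion", "neuroblastoma"),
                         states = c("resting", "action"),
                         n_steps = 2000, method = "fixed_point") {
  out <- list()
  summ <- list()
  for (cell in cells) {
    for (state in states) {
      inputs <- load_preset(cell, state)
      sol <- solve_surface_potentials(inputs, method = method)
      prof <- assemble_profile(inputs, sol, n_steps = n_steps)
      key <- paste(cell, state, sep = "_")
      out[[key]] <- prof
      summ[[key]] <- data.frame(
        cell = cell, state = state,
        psi1_mV = .statV_to_mV(sol$psi1),
        psi2_mV = .statV_to_mV(sol$psi2),
        psi3_mV = .statV_to_mV(sol$psi3),
        delta_glyco_mV = .statV_to_mV(sol$psi2 - sol$psi1),
        delta_S2_model_mV = .statV_to_mV(prof$diagnostics$delta_S2_model),
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "summary") <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
  out
}

#' Write a sweep result to CSV
#'
#' Comma-separated, '.' decimal, UTF-8, header row; sweep metadata is
#' written to a `<path>.json` sidecar (including the ratio-axis
#' direction: r scales the negative base charge, so larger r means more
#' negative charge).
#'
#' @param result a `sweep_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = FALSE)
  spec <- attr(result, "spec")
  meta <- list(
    swept_quantity = spec$swept_quantity,
    ratio_semantics = "charge = ratio * preset base (base negative; larger ratio = more negative charge)",
    ratio_grid = spec$ratio_grid,
    cells = spec$cells, states = spec$states)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
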