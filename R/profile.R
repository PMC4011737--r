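# Fixed-step 4th-order Runge-Kutta integration of the regional ODEs and
# assembly of the four-region potential profile.

#' Integrate a regional first-integral ODE with classical RK4
#'
#' Fixed-step fourth-order Runge-Kutta on dpsi/dx = slope(psi) from
#' `x_start` to `x_end` (either direction).  Both endpoints are included
#' in the returned samples.
#'
#' @param ode a [region_ode()] whose `boundary_point$x` equals `x_start`.
#' @param x_start,x_end integration bounds, cm.
#' @param n_steps number of RK4 steps (>= 2).
#' @param stop_when optional predicate `function(psi)`; integration halts
#'   after the first accepted step for which it is `TRUE`.
#' @return data.frame with columns `x` (cm) and `psi` (statV).
#' @export
integrate_region <- function(ode, x_start, x_end, n_steps,
                             stop_when = NULL) {
  stopifnot(n_steps >= 2)
  h <- (x_end - x_start) / n_steps
  x <- numeric(n_steps + 1)
  psi <- numeric(n_steps + 1)
  x[1] <- x_start
  psi[1] <- ode$boundary_point$psi
  f <- function(p) slope(ode, p)
  m <- 1L
  for (i in seq_len(n_steps)) {
    k1 <- f(psi[m])
    k2 <- f(psi[m] + h / 2 * k1)
    k3 <- f(psi[m] + h / 2 * k2)
    k4 <- f(psi[m] + h * k3)
    psi[m + 1L] <- psi[m] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x[m + 1L] <- x_start + i * h
    m <- m + 1L
    if (!is.null(stop_when) && isTRUE(stop_when(psi[m]))) break
  }
  data.frame(x = x[seq_len(m)], psi = psi[seq_len(m)])
}

# default truncation of the semi-infinite bulk regions
.bulk_extent <- function(ions, dielectric, constants) {
  max(10 * debye_length(ions, dielectric, constants), 20e-7)
}

#' Assemble the full four-region potential profile
#'
#' Builds a continuous sampled profile from converged surface potentials:
#' the extracellular diffuse layer is integrated outward from (S1, psi1)
#' until the potential has decayed below 0.1% of |psi1|, the glycocalyx
#' is integrated forward from its S1 anchor (psi1 and the jump-consistent
#' S1 field) across the slab, the bilayer is the exact chord from the
#' landed glycocalyx value at S2 to psi3, and the cytoplasmic diffuse
#' layer is integrated inward from (S3, psi3) until the potential is
#' within 0.1% of the transmembrane potential.
#'
#' Because the surface-potential system constrains fields and potentials
#' but not the glycocalyx width, the glycocalyx trajectory generally
#' lands at S2 on a value differing from psi2 by a model-consistency gap;
#' the assembled profile stays continuous by construction and the gap is
#' reported in `diagnostics$delta_S2_model` rather than silently
#' resolved.  (S1 anchoring is used because the forward trajectory is
#' contracting toward the slow Donnan manifold; anchoring at S2 and
#' integrating backward amplifies rounding into large spurious gaps.
#' The backward alternative is still computed as a diagnostic.)
#'
#' @param inputs a [model_inputs()] object.
#' @param surfaces a converged `surface_potentials` object.
#' @param domain_extent optional truncation distance (cm) for each bulk
#'   region; defaults to max(10 Debye lengths, 20 nm).
#' @param n_steps RK4 steps per region.
#' @return object of class `potential_profile`.
#' @export
assemble_profile <- function(inputs, surfaces, domain_extent = NULL,
                             n_steps = 2000) {
  if (!inherits(surfaces, "surface_potentials")) {
    stop("surfaces must come from solve_surface_potentials()")
  }
  if (.statV_to_mV(surfaces$residual_F) > 1e-3) {
    stop("surface potentials not converged")
  }
  cst <- inputs$constants
  geo <- inputs$geometry
  cs <- .coef_set(inputs)
  psi1 <- surfaces$psi1
  psi2 <- surfaces$psi2
  psi3 <- surfaces$psi3
  dpsi <- inputs$state$transmembrane_potential
  fl <- .surface_fields(inputs, psi2, psi3)

  ext_e <- if (is.null(domain_extent)) {
    .bulk_extent(inputs$ions$e, inputs$dielectrics$e, cst)
  } else domain_extent
  ext_c <- if (is.null(domain_extent)) {
    .bulk_extent(inputs$ions$c, inputs$dielectrics$c, cst)
  } else domain_extent

  # glycocalyx: anchored at (S1, psi1) with the jump-consistent S1 field,
  # integrated forward across the slab (contracting direction)
  Kg <- glycocalyx_constant(psi1, fl$E_g_S1, cs$g, cst)
  ode_g <- region_ode("g", cs$g, Kg,
                      slope_sign = if (fl$E_g_S1 >= 0) -1 else 1,
                      boundary_point = list(x = geo$x_S1, psi = psi1),
                      constants = cst)
  seg_g <- integrate_region(ode_g, geo$x_S1, geo$x_S2, n_steps)
  psi_land_S2 <- seg_g$psi[nrow(seg_g)]
  delta_S2_model <- abs(psi_land_S2 - psi2)

  # alternative anchoring at (S2, psi2), integrated backward: secondary
  # width-consistency diagnostic (numerically delicate near the Donnan
  # slow manifold, hence tryCatch)
  Kg_alt <- glycocalyx_constant(psi2, fl$E_g_S2, cs$g, cst)
  ode_g_alt <- region_ode("g", cs$g, Kg_alt,
                          slope_sign = if (fl$E_g_S2 >= 0) -1 else 1,
                          boundary_point = list(x = geo$x_S2, psi = psi2),
                          constants = cst)
  seg_g_alt <- tryCatch(
    integrate_region(ode_g_alt, geo$x_S2, geo$x_S1, n_steps),
    error = function(e) NULL)
  delta_S1_alt <- if (is.null(seg_g_alt)) NA_real_ else
    abs(seg_g_alt$psi[nrow(seg_g_alt)] - psi1)

  # extracellular: anchored at (S1, psi1), integrated outward
  Ke <- extracellular_constant(cs$e, 0, cst)
  sgn_e <- if (psi1 == 0) 1 else sign(psi1)
  ode_e <- region_ode("e", cs$e, Ke, slope_sign = sgn_e,
                      boundary_point = list(x = geo$x_S1, psi = psi1),
                      constants = cst)
  thr_e <- 1e-3 * abs(psi1)
  seg_e <- integrate_region(ode_e, geo$x_S1, geo$x_S1 - ext_e, n_steps,
                            stop_when = function(p) abs(p) < thr_e)
  seg_e <- seg_e[rev(seq_len(nrow(seg_e))), ]

  # bilayer: exact chord from the landed glycocalyx value to psi3
  xb <- seq(geo$x_S2, geo$x_S3, length.out = max(n_steps %/% 4, 2) + 1)
  seg_b <- data.frame(x = xb, psi = bilayer_profile(psi_land_S2, psi3, geo, xb))

  # cytoplasm: anchored at (S3, psi3), integrated inward until within
  # 0.1% of the transmembrane potential
  Kc <- cytoplasm_constant(cs$c, dpsi, cst)
  sgn_c <- if (psi3 == dpsi) 1 else sign(dpsi - psi3)
  ode_c <- region_ode("c", cs$c, Kc, slope_sign = sgn_c,
                      boundary_point = list(x = geo$x_S3, psi = psi3),
                      constants = cst)
  thr_c <- 1e-3 * max(abs(dpsi), .mV_to_statV(1))
  seg_c <- integrate_region(ode_c, geo$x_S3, geo$x_S3 + ext_c, n_steps,
                            stop_when = function(p) abs(p - dpsi) < thr_c)

  stitch <- function(a, b) {
    # interfaces appear exactly once, owned by the left segment
    rbind(a, b[-1, , drop = FALSE])
  }
  samples <- stitch(stitch(stitch(
    cbind(seg_e, region = "e"), cbind(seg_g, region = "g")),
    cbind(seg_b, region = "b")), cbind(seg_c, region = "c"))
  rownames(samples) <- NULL

  interface_values <- data.frame(
    surface = c("S1", "S2", "S3"),
    x = c(geo$x_S1, geo$x_S2, geo$x_S3),
    psi_left = c(seg_e$psi[nrow(seg_e)], seg_g$psi[nrow(seg_g)],
                 seg_b$psi[nrow(seg_b)]),
    psi_right = c(seg_g$psi[1], seg_b$psi[1], seg_c$psi[1]))

  structure(list(
    samples = samples,
    interfaces = c(x_S1 = geo$x_S1, x_S2 = geo$x_S2, x_S3 = geo$x_S3),
    interface_values = interface_values,
    surface_potentials = surfaces,
    state = inputs$state,
    n_steps = n_steps,
    diagnostics = list(
      delta_S2_model = delta_S2_model,
      delta_S1_alt_anchor = delta_S1_alt,
      psi_land_S2 = psi_land_S2,
      extent_e = ext_e, extent_c = ext_c,
      thresholds = c(e = thr_e, c = thr_c))
  ), class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  sp <- x$surface_potentials
  cat("Potential profile (", sp$cell_name, "/", x$state$label, "), ",
      nrow(x$samples), " samples\n", sep = "")
  cat(sprintf("  x range: %.2f .. %.2f nm; psi range: %.2f .. %.2f mV\n",
              min(x$samples$x) * 1e7, max(x$samples$x) * 1e7,
              .statV_to_mV(min(x$samples$psi)),
              .statV_to_mV(max(x$samples$psi))))
  cat(sprintf("  psi1/psi2/psi3: %.3f / %.3f / %.3f mV\n",
              .statV_to_mV(sp$psi1), .statV_to_mV(sp$psi2),
              .statV_to_mV(sp$psi3)))
  cat(sprintf("  glycocalyx width-consistency gap at S2: %.4f mV\n",
              .statV_to_mV(x$diagnostics$delta_S2_model)))
  invisible(x)
}

#' @export
as.data.frame.potential_profile <- function(x, ...) {
  data.frame(x_nm = x$samples$x * 1e7,
             psi_mV = .statV_to_mV(x$samples$psi),
             region = x$samples$region)
}

#' Validate an assembled potential profile
#'
#' Recomputes all structural invariants: sample ordering, continuity at
#' the three interfaces, Gauss jump residuals of the converged surface
#' solution, bilayer linearity, bulk limiting values, extracellular
#' monotone decay, interior sample smoothness (flags injected
#' corruption), and RK4 step-halving convergence.
#'
#' @param profile a `potential_profile`.
#' @param inputs the [model_inputs()] the profile was built from.
#' @param check_convergence re-integrate at doubled step count and
#'   compare (default `TRUE`).
#' @return a `validation_report`.
#' @export
validate_profile <- function(profile, inputs, check_convergence = TRUE) {
  rows <- list()
  add <- function(check, residual, tol, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, pass = is.finite(residual) && residual <= tol,
      severity = "error", residual = residual, note = note,
      stringsAsFactors = FALSE)
  }
  s <- profile$samples
  add("x strictly increasing",
      as.numeric(any(diff(s$x) <= 0)), 0)
  iv <- profile$interface_values
  for (i in seq_len(nrow(iv))) {
    add(paste0("continuity at ", iv$surface[i]),
        .statV_to_mV(abs(iv$psi_left[i] - iv$psi_right[i])), 1e-6,
        sprintf("x = %.3f nm", iv$x[i] * 1e7))
  }
  # samples at the interface x must agree with the recorded interface values
  for (i in seq_len(nrow(iv))) {
    at <- s$psi[abs(s$x - iv$x[i]) < 1e-12 * max(abs(iv$x[i]), 1e-7)]
    res <- if (length(at) == 0) Inf else
      .statV_to_mV(max(abs(at - iv$psi_right[i])))
    add(paste0("interface sample matches ", iv$surface[i]), res, 1e-6,
        sprintf("x = %.3f nm", iv$x[i] * 1e7))
  }
  jr <- profile$surface_potentials$jump_residuals
  field_scale <- max(abs(c(4 * pi * inputs$charges$sigma1,
                           4 * pi * inputs$charges$sigma2,
                           4 * pi * inputs$charges$sigma3) /
                           unlist(inputs$dielectrics)[c("g", "b", "c")]), 1)
  add("jump conditions (max over S1..S3)",
      max(abs(jr)) / field_scale, 1e-8)
  # bilayer linearity: deviation from the chord
  b <- s[s$region == "b", ]
  chord <- b$psi[1] + (b$psi[nrow(b)] - b$psi[1]) *
    (b$x - b$x[1]) / (b$x[nrow(b)] - b$x[1])
  add("bilayer linearity",
      max(abs(b$psi - chord)) / max(abs(b$psi), 1e-30), 1e-12)
  # bulk limits
  psi1 <- profile$surface_potentials$psi1
  dpsi <- inputs$state$transmembrane_potential
  add("extracellular bulk limit",
      abs(s$psi[1]) / max(abs(psi1), .mV_to_statV(1)), 1e-3)
  add("cytoplasmic bulk limit",
      abs(s$psi[nrow(s)] - dpsi) / max(abs(dpsi), .mV_to_statV(1)), 1e-3)
  # monotone decay of |psi| with distance from S1 in the bath
  e <- s[s$region == "e", ]
  add("extracellular monotone decay",
      as.numeric(any(diff(abs(e$psi)) < -1e-15)), 0)
  # interior smoothness: second differences should be tiny on the RK grid;
  # a corrupted sample produces an isolated spike
  spike <- 0
  spike_note <- ""
  for (rg in c("e", "g", "c")) {
    r <- s[s$region == rg, ]
    if (nrow(r) < 5) next
    d2 <- abs(diff(r$psi, differences = 2))
    thr <- max(50 * stats::median(d2), .mV_to_statV(0.05))
    if (any(d2 > thr)) {
      spike <- max(spike, max(d2 / thr))
      bad_x <- r$x[which.max(d2) + 1L]
      spike_note <- sprintf("discontinuity near x = %.4f nm (region %s)",
                            bad_x * 1e7, rg)
    }
  }
  add("sample smoothness", spike, 1, spike_note)
  if (check_convergence) {
    prof2 <- assemble_profile(inputs, profile$surface_potentials,
                              n_steps = 2L * profile$n_steps)
    s2 <- prof2$samples
    common <- merge(round(data.frame(x = s$x, psi = s$psi), 15),
                    round(data.frame(x = s2$x, psi2 = s2$psi), 15),
                    by = "x")
    add("step-halving convergence",
        .statV_to_mV(max(abs(common$psi - common$psi2))), 1e-8)
  }
  structure(list(table = do.call(rbind, rows),
                 subject = paste0(profile$surface_potentials$cell_name,
                                  "/", profile$state$label)),
            class = "validation_report")
}

#' Write a profile to CSV with a JSON metadata sidecar
#'
#' @param profile a `potential_profile`.
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sp <- profile$surface_potentials
  meta <- list(
    cell = sp$cell_name, state = profile$state$label,
    psi1_mV = .statV_to_mV(sp$psi1), psi2_mV = .statV_to_mV(sp$psi2),
    psi3_mV = .statV_to_mV(sp$psi3),
    fixed_point_residual_mV = .statV_to_mV(sp$residual_F),
    jump_residuals_statV_cm = as.list(sp$jump_residuals),
    delta_S2_model_mV = .statV_to_mV(profile$diagnostics$delta_S2_model),
    interfaces_nm = as.list(profile$interfaces * 1e7),
    n_steps = profile$n_steps,
    software = paste0("membranepb ",
                      as.character(utils::packageVersion("membranepb")))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
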