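# Surface potentials psi1, psi2, psi3.
#
# psi1 follows from the electrophoretic mobility via the
# Helmholtz-Smoluchowski zeta potential.  psi2 and psi3 solve a 2x2
# nonlinear system built from the Gauss-law field discontinuities at S2
# and S3 combined with the glycocalyx and cytoplasm first integrals:
#
#   S2:  eps_b E_m - eps_g E_g(S2) = 4 pi sigma2,   E_m = (psi2-psi3)/hb
#   S3:  eps_c E_c(S3) - eps_b E_m = 4 pi sigma3
#
# where |E_g(S2)| and |E_c(S3)| come from the first integrals anchored at
# (psi1, E_g(S1)) and at the bulk cytoplasm respectively, and E_g(S1) is
# itself fixed by the S1 jump from the extracellular diffuse layer.

#' Surface potential on S1 from the electrophoretic mobility
#'
#' Helmholtz-Smoluchowski: zeta = 4 pi eta mu / eps.  With the
#' extracellular bulk potential defined as zero, psi1 equals zeta offset
#' by that bulk value.
#'
#' @param kinetics list with `electrophoretic_mobility` (cm^2/(statV s))
#'   and `viscosity_eta` (poise).
#' @param dielectric relative permittivity of the aqueous medium.
#' @param psi_extracellular_bulk bulk potential, statV (0 by convention).
#' @return psi1 in statV.
#' @export
psi1_from_mobility <- function(kinetics, dielectric,
                               psi_extracellular_bulk = 0) {
  if (kinetics$viscosity_eta <= 0) stop("viscosity must be positive")
  zeta <- 4 * pi * kinetics$viscosity_eta *
    kinetics$electrophoretic_mobility / dielectric
  psi_extracellular_bulk + zeta
}

#' Residual of a Gauss-law field discontinuity
#'
#' For the jump relation eps_right E_right - eps_left E_left = 4 pi sigma
#' across a charged surface, returns the signed residual
#' (eps_left E_left + 4 pi sigma - eps_right E_right) / max(eps), which is
#' zero on an exact solution and reduces to field_left - field_right for
#' an uncharged surface between equal dielectrics.
#'
#' @param cond list with `surface`, `sigma` (statC/cm^2), `eps_left`,
#'   `eps_right`, `field_left`, `field_right` (statV/cm).
#' @return residual in statV/cm.
#' @export
check_jump <- function(cond) {
  (cond$eps_left * cond$field_left + 4 * pi * cond$sigma -
     cond$eps_right * cond$field_right) / max(cond$eps_left, cond$eps_right)
}

# --- internal field helpers -------------------------------------------------

.coef_set <- function(inputs) {
  list(
    e = region_coefficients(inputs$ions$e, 0, inputs$dielectrics$e,
                            inputs$constants, region = "e"),
    g = region_coefficients(inputs$ions$g, inputs$charges$rho_f_g,
                            inputs$dielectrics$g, inputs$constants,
                            region = "g"),
    c = region_coefficients(inputs$ions$c, inputs$charges$rho_f_c,
                            inputs$dielectrics$c, inputs$constants,
                            region = "c")
  )
}

# extracellular-side field at S1 (E = -dpsi/dx); the diffuse layer decays
# to the bulk value 0, so the slope at S1 carries the sign of psi1
.field_e_S1 <- function(psi1, coeffs_e, constants) {
  Ke <- extracellular_constant(coeffs_e, 0, constants)
  s2 <- .pb_energy(psi1, coeffs_e, constants) + Ke$K
  s2 <- max(s2, 0)
  -sign(psi1) * sqrt(s2)   # dpsi/dx = sign(psi1)*sqrt, E = -dpsi/dx
}

# glycocalyx-side field at S1 via the S1 jump
.field_g_S1 <- function(inputs, coeffs_e = NULL) {
  if (is.null(coeffs_e)) coeffs_e <- .coef_set(inputs)$e
  psi1 <- inputs$ions$g$psi_bound
  Ee <- .field_e_S1(psi1, coeffs_e, inputs$constants)
  (inputs$dielectrics$e * Ee + 4 * pi * inputs$charges$sigma1) /
    inputs$dielectrics$g
}

# squared glycocalyx-side field at psi2, first integral anchored at
# (psi1, E_g(S1)); vectorized in psi2.  May be negative (unreachable).
.field_g_sq <- function(psi2, inputs, cs, Eg1) {
  .pb_energy(psi2, cs$g, inputs$constants) -
    .pb_energy(inputs$ions$g$psi_bound, cs$g, inputs$constants) + Eg1^2
}

# squared cytoplasm-side field at psi3, first integral anchored at the
# bulk transmembrane potential; vectorized in psi3
.field_c_sq <- function(psi3, inputs, cs) {
  dpsi <- inputs$state$transmembrane_potential
  .pb_energy(psi3, cs$c, inputs$constants) -
    .pb_energy(dpsi, cs$c, inputs$constants)
}

.default_window <- function() .mV_to_statV(c(-200, 100))

# locate roots of a vectorized function on a grid: sign changes refined
# with uniroot, plus exact tangential zeros accepted at supplied
# candidate points; candidates win over nearby refined grid roots
.grid_roots <- function(f, grid, scale, candidates = numeric(0),
                        tol = 1e-9 * .STATV_PER_MV) {
  cand_roots <- candidates[vapply(candidates,
                                  function(c) abs(f(c)) <= 1e-14 * scale,
                                  logical(1))]
  vals <- f(grid)
  ok <- is.finite(vals)
  idx <- which(ok[-length(ok)] & ok[-1] &
                 vals[-length(vals)] * vals[-1] < 0)
  grid_roots <- vapply(idx, function(i) {
    stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                   f.lower = vals[i], f.upper = vals[i + 1],
                   tol = tol)$root
  }, numeric(1))
  near_cand <- function(r) {
    length(cand_roots) && min(abs(r - cand_roots)) <= 0.05 * .STATV_PER_MV
  }
  if (length(grid_roots)) {
    grid_roots <- grid_roots[!vapply(grid_roots, near_cand, logical(1))]
  }
  roots <- c(cand_roots, grid_roots)
  if (length(roots) > 1) {
    keep <- !duplicated(round(roots / (10 * tol)))
    roots <- roots[keep]
  }
  roots
}

.pick_root <- function(roots, target, label) {
  if (length(roots) == 0) {
    stop("no root in window for ", label,
         " (potential outside reachable branch)")
  }
  if (length(roots) > 1) {
    attr(roots, "multiplicity") <- length(roots)
  }
  r <- roots[which.min(abs(roots - target))]
  attr(r, "n_roots") <- length(roots)
  r
}

#' Map G: surface potential psi2 given psi3
#'
#' Solves the S2 jump condition combined with the glycocalyx first
#' integral (anchored at S1) for psi2.  If several roots lie in the scan
#' window, the one closest to `prev` (or to psi1) is returned, with the
#' root count attached as attribute `n_roots`.
#'
#' @param psi3 surface potential on S3, statV.
#' @param inputs a [model_inputs()] object.
#' @param window scan window in statV (default -200..100 mV).
#' @param prev previous iterate used for root selection, or `NULL`.
#' @return psi2 in statV.
#' @export
surface_map_G <- function(psi3, inputs, window = .default_window(),
                          prev = NULL) {
  cs <- .coef_set(inputs)
  Eg1 <- .field_g_S1(inputs, cs$e)
  hb <- inputs$geometry$hb
  eb <- inputs$dielectrics$b
  eg <- inputs$dielectrics$g
  s2 <- inputs$charges$sigma2
  f <- function(psi2) {
    Em <- (psi2 - psi3) / hb
    eg^2 * .field_g_sq(psi2, inputs, cs, Eg1) - (eb * Em - 4 * pi * s2)^2
  }
  scale <- eg^2 * (abs(.pb_energy(window[1], cs$g, inputs$constants)) +
                     abs(Eg1)^2 + 1)
  grid <- seq(window[1], window[2], by = 0.1 * .STATV_PER_MV)
  psi1 <- inputs$ions$g$psi_bound
  target <- if (is.null(prev)) psi1 else prev
  roots <- .grid_roots(f, grid, scale, candidates = unique(c(psi1, prev)))
  # branch convention: the squared jump relation is blind to the field
  # sign, so a mirror root on the far side of psi1 always coexists;
  # keep the monotone-slab branch, where the S2 field points from psi1
  # toward psi2 (matching the monotone glycocalyx profiles of the model)
  if (length(roots)) {
    Eg2_req <- (eb * (roots - psi3) / hb - 4 * pi * s2) / eg
    ok <- (psi1 - roots) * Eg2_req >= 0 |
      abs(roots - psi1) < 1e-9 * .STATV_PER_MV
    roots <- roots[ok]
  }
  .pick_root(roots, target, "psi2 (map G)")
}

#' Map F: surface potential psi3 given psi2
#'
#' Mirror of [surface_map_G()]: solves the S3 jump condition combined
#' with the cytoplasm first integral for psi3.  Root selection prefers
#' `prev`, falling back to the transmembrane potential.
#'
#' @param psi2 surface potential on S2, statV.
#' @inheritParams surface_map_G
#' @return psi3 in statV.
#' @export
surface_map_F <- function(psi2, inputs, window = .default_window(),
                          prev = NULL) {
  cs <- .coef_set(inputs)
  hb <- inputs$geometry$hb
  eb <- inputs$dielectrics$b
  ec <- inputs$dielectrics$c
  s3 <- inputs$charges$sigma3
  dpsi <- inputs$state$transmembrane_potential
  f <- function(psi3) {
    Em <- (psi2 - psi3) / hb
    ec^2 * .field_c_sq(psi3, inputs, cs) - (4 * pi * s3 + eb * Em)^2
  }
  scale <- ec^2 * (abs(.pb_energy(window[1], cs$c, inputs$constants)) + 1)
  grid <- seq(window[1], window[2], by = 0.1 * .STATV_PER_MV)
  target <- if (is.null(prev)) dpsi else prev
  roots <- .grid_roots(f, grid, scale, candidates = unique(c(dpsi, prev)))
  # branch validity: the semi-infinite cytoplasm must approach its bulk
  # value, so the S3 slope (-E_c required by the jump) has to point from
  # psi3 toward the transmembrane potential
  if (length(roots)) {
    Ec_req <- (4 * pi * s3 + eb * (psi2 - roots) / hb) / ec
    ok <- (dpsi - roots) * (-Ec_req) >= 0 |
      abs(dpsi - roots) < 1e-9 * .STATV_PER_MV
    roots <- roots[ok]
  }
  .pick_root(roots, target, "psi3 (map F)")
}

# all interface fields for a candidate (psi2, psi3); used for jump checks
.surface_fields <- function(inputs, psi2, psi3) {
  cs <- .coef_set(inputs)
  psi1 <- inputs$ions$g$psi_bound
  Ee1 <- .field_e_S1(psi1, cs$e, inputs$constants)
  Eg1 <- .field_g_S1(inputs, cs$e)
  Em <- (psi2 - psi3) / inputs$geometry$hb
  # sides required by the jump relations fix the field signs
  Eg2_req <- (inputs$dielectrics$b * Em - 4 * pi * inputs$charges$sigma2) /
    inputs$dielectrics$g
  Ec3_req <- (inputs$dielectrics$b * Em + 4 * pi * inputs$charges$sigma3) /
    inputs$dielectrics$c
  Eg2_fi <- sign(Eg2_req) * sqrt(max(.field_g_sq(psi2, inputs, cs, Eg1), 0))
  Ec3_fi <- sign(Ec3_req) * sqrt(max(.field_c_sq(psi3, inputs, cs), 0))
  list(E_e_S1 = Ee1, E_g_S1 = Eg1, E_m = Em,
       E_g_S2 = Eg2_fi, E_c_S3 = Ec3_fi,
       E_g_S2_required = Eg2_req, E_c_S3_required = Ec3_req)
}

# the three jump residuals (statV/cm, dielectric-normalized) evaluated
# with first-integral fields on the aqueous sides
.jump_residuals <- function(inputs, psi2, psi3) {
  fl <- .surface_fields(inputs, psi2, psi3)
  d <- inputs$dielectrics
  ch <- inputs$charges
  c(
    S1 = check_jump(list(surface = "S1", sigma = ch$sigma1,
                         eps_left = d$e, eps_right = d$g,
                         field_left = fl$E_e_S1, field_right = fl$E_g_S1)),
    S2 = check_jump(list(surface = "S2", sigma = ch$sigma2,
                         eps_left = d$g, eps_right = d$b,
                         field_left = fl$E_g_S2, field_right = fl$E_m)),
    S3 = check_jump(list(surface = "S3", sigma = ch$sigma3,
                         eps_left = d$b, eps_right = d$c,
                         field_left = fl$E_m, field_right = fl$E_c_S3))
  )
}

#' Solve the nonlinear system for the surface potentials
#'
#' Computes psi1 from the electrophoretic mobility, then solves the
#' two-variable system psi2 = G(psi3), psi3 = F(psi2) either with the
#' scan-and-iterate fixed-point heuristic (`"fixed_point"`, the
#' default: successive substitution with a shrinking acceptance band,
#' restarting from scanned initial values on divergence) or with a
#' deterministic bracketed root solve on h(psi3) = F(G(psi3)) - psi3
#' (`"bracketed_fallback"`).
#'
#' @param inputs a [model_inputs()] object.
#' @param method `"fixed_point"` or `"bracketed_fallback"`.
#' @param eps_mV convergence tolerance on the fixed-point residual, mV.
#' @param delta0_mV initial acceptance band for the iteration, mV.
#' @param window_mV scan window for psi3, mV.
#' @param scan_step_mV spacing of restart values across the window, mV.
#' @param max_iter iteration cap per start value.
#' @return object of class `surface_potentials` with fields `psi1`,
#'   `psi2`, `psi3` (statV), fixed-point and jump residuals, iteration
#'   count, method and warnings.
#' @export
solve_surface_potentials <- function(inputs,
                                     method = c("fixed_point",
                                                "bracketed_fallback"),
                                     eps_mV = 1e-4, delta0_mV = 20,
                                     window_mV = c(-200, 100),
                                     scan_step_mV = 0.1,
                                     max_iter = 100L) {
  method <- match.arg(method)
  window <- .mV_to_statV(window_mV)
  eps <- .mV_to_statV(eps_mV)
  psi1 <- psi1_from_mobility(inputs$kinetics, inputs$dielectrics$e, 0)
  if (!isTRUE(all.equal(psi1, inputs$ions$g$psi_bound, tolerance = 1e-9,
                        scale = max(abs(psi1), 1e-12)))) {
    # keep the glycocalyx reference pair consistent with the mobility
    inputs$ions$g$psi_bound <- psi1
  }
  warnings <- character(0)
  note_roots <- function(x) {
    n <- attr(x, "n_roots")
    if (!is.null(n) && n > 1) {
      warnings <<- unique(c(warnings,
                            sprintf("multiple roots in window (%d); nearest selected", n)))
    }
    as.numeric(x)
  }
  dpsi <- inputs$state$transmembrane_potential
  iterations <- 0L
  psi2 <- psi3 <- NA_real_

  run_fp <- function(start) {
    psi3 <- start
    psi2 <- NULL
    delta <- .mV_to_statV(delta0_mV)
    for (it in seq_len(max_iter)) {
      iterations <<- iterations + 1L
      psi2_new <- note_roots(surface_map_G(psi3, inputs, window, prev = psi2))
      psi3_new <- note_roots(surface_map_F(psi2_new, inputs, window,
                                           prev = psi3))
      d <- abs(psi3_new - psi3)
      if (d >= delta) return(NULL)        # diverging: restart (Step 1)
      delta <- max(d, eps)
      psi2 <- psi2_new
      psi3 <- psi3_new
      if (d < eps) return(list(psi2 = psi2, psi3 = psi3))
    }
    NULL
  }

  if (method == "fixed_point") {
    # Step-1 scan order: start at the transmembrane potential, then walk
    # the window on the restart grid
    starts <- c(dpsi, seq(window[1], window[2],
                          by = .mV_to_statV(scan_step_mV) * 50))
    sol <- NULL
    for (s in starts) {
      sol <- tryCatch(run_fp(s), error = function(e) NULL)
      if (!is.null(sol)) break
    }
    if (is.null(sol)) {
      # exhaustive restart: dense scan of initial values across the window
      starts <- seq(window[1], window[2], by = .mV_to_statV(scan_step_mV) * 10)
      for (s in starts) {
        sol <- tryCatch(run_fp(s), error = function(e) NULL)
        if (!is.null(sol)) break
      }
    }
    if (is.null(sol)) stop("no root in window: fixed-point scan exhausted")
    psi2 <- sol$psi2
    psi3 <- sol$psi3
  } else {
    h <- function(p3) {
      p2 <- note_roots(surface_map_G(p3, inputs, window, prev = NULL))
      note_roots(surface_map_F(p2, inputs, window, prev = p3)) - p3
    }
    grid <- seq(window[1], window[2], by = .mV_to_statV(1))
    vals <- vapply(grid, function(g) tryCatch(h(g), error = function(e) NA_real_),
                   numeric(1))
    iterations <- iterations + length(grid)
    ok <- which(!is.na(vals))
    segs <- ok[which(diff(ok) == 1 &
                       vals[ok[-length(ok)]] * vals[ok[-1]] <= 0)]
    if (length(segs) == 0) stop("no root in window (bracketed fallback)")
    # prefer the bracket nearest the transmembrane potential
    segs <- segs[order(abs(grid[segs] - dpsi))]
    i <- segs[1]
    psi3 <- stats::uniroot(h, lower = grid[i], upper = grid[i + 1],
                           tol = .mV_to_statV(1e-6))$root
    psi2 <- note_roots(surface_map_G(psi3, inputs, window, prev = NULL))
  }

  # polish: successive substitution is strongly contracting here, so a
  # few extra sweeps drive the fixed-point residual far below the
  # nominal epsilon and let the Gauss jump conditions close to ~1e-8 of
  # the field scale
  for (k in seq_len(20L)) {
    p2n <- tryCatch(as.numeric(surface_map_G(psi3, inputs, window,
                                             prev = psi2)),
                    error = function(e) NA_real_)
    if (!is.finite(p2n)) break
    p3n <- tryCatch(as.numeric(surface_map_F(p2n, inputs, window,
                                             prev = psi3)),
                    error = function(e) NA_real_)
    if (!is.finite(p3n)) break
    d <- abs(p3n - psi3)
    psi2 <- p2n
    psi3 <- p3n
    iterations <- iterations + 1L
    if (d < .mV_to_statV(1e-9)) break
  }

  psi2_chk <- note_roots(surface_map_G(psi3, inputs, window, prev = psi2))
  psi3_chk <- note_roots(surface_map_F(psi2_chk, inputs, window, prev = psi3))
  res_G <- abs(psi2_chk - psi2)
  res_F <- abs(psi3_chk - psi3)
  jumps <- .jump_residuals(inputs, psi2, psi3)
  structure(list(
    psi1 = psi1, psi2 = psi2, psi3 = psi3,
    residual_F = res_F, residual_G = res_G,
    jump_residuals = jumps,
    iterations = iterations, method = method,
    warnings = warnings,
    cell_name = inputs$cell_name, state = inputs$state$label
  ), class = "surface_potentials")
}

#' @export
print.surface_potentials <- function(x, ...) {
  cat("Surface potentials (", x$cell_name, "/", x$state, ", ",
      x$method, ")\n", sep = "")
  cat(sprintf("  psi1 = %9.4f mV\n  psi2 = %9.4f mV\n  psi3 = %9.4f mV\n",
              .statV_to_mV(x$psi1), .statV_to_mV(x$psi2),
              .statV_to_mV(x$psi3)))
  cat(sprintf("  fixed-point residual: %.3g mV in %d iterations\n",
              .statV_to_mV(x$residual_F), x$iterations))
  cat(sprintf("  jump residuals (statV/cm): S1 %.3g, S2 %.3g, S3 %.3g\n",
              x$jump_residuals[["S1"]], x$jump_residuals[["S2"]],
              x$jump_residuals[["S3"]]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a solver result to a JSON-style record
#'
#' @param x a `surface_potentials` object.
#' @return a JSON string (mV scale for the potentials).
#' @export
surface_record_json <- function(x) {
  jsonlite::toJSON(list(
    cell = x$cell_name, state = x$state, method = x$method,
    psi1_mV = .statV_to_mV(x$psi1), psi2_mV = .statV_to_mV(x$psi2),
    psi3_mV = .statV_to_mV(x$psi3),
    fixed_point_residual_mV = .statV_to_mV(x$residual_F),
    jump_residuals_statV_cm = as.list(x$jump_residuals),
    iterations = x$iterations, warnings = x$warnings
  ), auto_unbox = TRUE, digits = NA)
}

# Independent brute-force oracle: hierarchically refined dense 2-D grid
# minimization of the two jump-balance residuals, down to `final_res_mV`
# resolution.  Used only by tests; independent of the fixed-point path.
.grid_search_surface <- function(inputs, window_mV = c(-80, 40),
                                 final_res_mV = 1e-3) {
  cs <- .coef_set(inputs)
  Eg1 <- .field_g_S1(inputs, cs$e)
  hb <- inputs$geometry$hb
  d <- inputs$dielectrics
  ch <- inputs$charges
  resid2 <- function(p2, p3) {
    Em <- outer(p2, p3, function(a, b) (a - b) / hb)
    G1 <- d$g^2 * .field_g_sq(p2, inputs, cs, Eg1)
    Eg2_req <- (d$b * Em - 4 * pi * ch$sigma2) / d$g
    R1 <- G1 - (d$g * Eg2_req)^2
    C1 <- d$c^2 * .field_c_sq(p3, inputs, cs)
    Ec_req <- (4 * pi * ch$sigma3 + d$b * Em) / d$c
    R2 <- t(t(-(d$c * Ec_req)^2) + C1)
    out <- abs(R1) + abs(R2)
    # mask cytoplasm-branch-invalid candidates (bulk approach condition)
    dpsi <- inputs$state$transmembrane_potential
    gap <- rep(dpsi - p3, each = length(p2))
    approach <- -Ec_req * gap
    out[approach < 0 & abs(gap) > 1e-9 * .STATV_PER_MV] <- Inf
    # mask glycocalyx mirror branch (same convention as surface_map_G)
    psi1 <- inputs$ions$g$psi_bound
    gap_g <- rep(psi1 - p2, times = length(p3))
    out[gap_g * Eg2_req < 0 &
          abs(gap_g) > 1e-9 * .STATV_PER_MV] <- Inf
    out
  }
  lo2 <- lo3 <- .mV_to_statV(window_mV[1])
  hi2 <- hi3 <- .mV_to_statV(window_mV[2])
  res <- .mV_to_statV(0.5)
  repeat {
    p2 <- seq(lo2, hi2, by = res)
    p3 <- seq(lo3, hi3, by = res)
    M <- resid2(p2, p3)
    ij <- arrayInd(which.min(M), dim(M))
    b2 <- p2[ij[1]]
    b3 <- p3[ij[2]]
    if (res <= .mV_to_statV(final_res_mV)) break
    span <- 3 * res
    lo2 <- b2 - span; hi2 <- b2 + span
    lo3 <- b3 - span; hi3 <- b3 + span
    res <- res / 20
    if (res < .mV_to_statV(final_res_mV)) res <- .mV_to_statV(final_res_mV)
  }
  c(psi2 = b2, psi3 = b3)
}
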