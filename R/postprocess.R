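## Scalar outcomes and field exports from converged states: herniated volume
## (two independent estimators), ICP estimators, midline shift, stress and
## displacement extrema. Reporting units follow the clinical conventions:
## ml, mm-Hg, mm, kPa.

## 6-point degree-4 triangle rule (barycentric points, weights sum to 1)
.tri_quadrature <- function() {
  a1 <- 0.445948490915965; b1 <- 0.108103018168070; w1 <- 0.223381589678011
  a2 <- 0.091576213509771; b2 <- 0.816847572980459; w2 <- 0.109951743655322
  L <- rbind(c(a1, a1, b1), c(a1, b1, a1), c(b1, a1, a1),
             c(a2, a2, b2), c(a2, b2, a2), c(b2, a2, a2))
  list(L = L, w = c(w1, w1, w1, w2, w2, w2) / 2) # folded ref-triangle area
}

## P2 shape values on a 6-node triangle (3 vertices + midsides 12, 23, 13)
.tri_p2 <- function(L) {
  cbind(L[, 1] * (2 * L[, 1] - 1), L[, 2] * (2 * L[, 2] - 1),
        L[, 3] * (2 * L[, 3] - 1),
        4 * L[, 1] * L[, 2], 4 * L[, 2] * L[, 3], 4 * L[, 1] * L[, 3])
}

## barycentric gradients on the reference triangle (d/dL2, d/dL3 with L1 dep.)
.tri_p2_grad <- function(L) {
  # parametrize by (s, t) = (L2, L3); dN/ds and dN/dt
  dNds <- cbind(-(4 * L[, 1] - 1), 4 * L[, 2] - 1, 0,
                4 * (L[, 1] - L[, 2]), 4 * L[, 3], -4 * L[, 3])
  dNdt <- cbind(-(4 * L[, 1] - 1), 0, 4 * L[, 3] - 1,
                -4 * L[, 2], 4 * L[, 2], 4 * (L[, 1] - L[, 3]))
  list(ds = dNds, dt = dNdt)
}

## P2 node ids (6) of boundary facets: vertices then midsides (12, 23, 13)
.facet_p2_nodes <- function(fe, facets) {
  nv <- fe$nv
  key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  mid <- function(a, b) nv + match(key(a, b), fe$edge_keys)
  cbind(facets,
        mid(facets[, 1], facets[, 2]),
        mid(facets[, 2], facets[, 3]),
        mid(facets[, 1], facets[, 3]))
}

## flux integral (1/3) * int x . n dA over curved P2 facets at positions xs
.cone_volume_integral <- function(xs, fnodes) {
  tq <- .tri_quadrature()
  N <- .tri_p2(tq$L)
  G <- .tri_p2_grad(tq$L)
  total <- 0
  for (q in seq_len(nrow(tq$L))) {
    P <- Ps <- Pt <- matrix(0, nrow(fnodes), 3)
    for (k in 1:6) {
      Xk <- xs[fnodes[, k], , drop = FALSE]
      P <- P + N[q, k] * Xk
      Ps <- Ps + G$ds[q, k] * Xk
      Pt <- Pt + G$dt[q, k] * Xk
    }
    nrm <- cbind(Ps[, 2] * Pt[, 3] - Ps[, 3] * Pt[, 2],
                 Ps[, 3] * Pt[, 1] - Ps[, 1] * Pt[, 3],
                 Ps[, 1] * Pt[, 2] - Ps[, 2] * Pt[, 1])
    total <- total + tq$w[q] * sum(rowSums(P * nrm))
  }
  total / 3
}

## deformation gradients, pressures and quadrature weights at all qps
.qp_fields <- function(state) {
  fe <- state$fe
  .cpp_qp_fields(fe$nodes, fe$cells10, fe$quad$weights, fe$dNu, fe$Np,
                 as.numeric(t(state$u)), state$p)
}

#' Herniated brain volume
#'
#' Primary estimator: the volume gained by the brain,
#' `int (det F - 1) dV0` over the reference domain. Since the skull
#' interface is fixed, any gained volume must protrude through the
#' craniectomy openings, which the secondary estimator measures directly as
#' the flux volume enclosed between the deformed and undeformed opening
#' patches. Disagreement beyond 2% flags an under-resolved mesh and attaches
#' a warning to the result.
#'
#' @param state A converged `solution_state`.
#' @param mesh The `labeled_mesh` the state was computed on (defaults to the
#'   mesh in the state).
#' @return A list: `ml` (primary estimate), `ml_surface` (secondary),
#'   `agreement` (relative difference), `warning` (logical).
#' @export
herniated_volume <- function(state, mesh = state$fe$mesh) {
  fe <- state$fe
  qp <- .qp_fields(state)
  Fm <- qp$F
  detF <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 6] * Fm[, 8]) -
          Fm[, 4] * (Fm[, 2] * Fm[, 9] - Fm[, 3] * Fm[, 8]) +
          Fm[, 7] * (Fm[, 2] * Fm[, 6] - Fm[, 3] * Fm[, 5])
  primary_m3 <- sum(qp$wdet * (detF - 1))
  fixed_tag <- mesh$tag_names[["fixed_interface"]]
  open_sel <- mesh$facet_tags != fixed_tag
  if (!any(open_sel)) {
    sec_m3 <- 0
  } else {
    fn <- .facet_p2_nodes(fe, mesh$facets[open_sel, , drop = FALSE])
    xs_ref <- fe$nodes
    xs_def <- fe$nodes + state$u
    sec_m3 <- .cone_volume_integral(xs_def, fn) -
      .cone_volume_integral(xs_ref, fn)
  }
  ml <- primary_m3 * 1e6
  ml_s <- sec_m3 * 1e6
  agree <- if (max(abs(ml), abs(ml_s)) < 1e-6) 0 else
    abs(ml - ml_s) / max(abs(ml), abs(ml_s))
  warn <- agree > 0.02
  if (warn)
    warning(sprintf(paste0("herniated-volume estimators disagree by %.1f%%; ",
                           "the mesh may be under-resolved"), 100 * agree))
  list(ml = ml, ml_surface = ml_s, agreement = agree, warning = warn)
}

#' Volume-averaged intracranial pressure loading
#'
#' The swelling-induced pressure increment above the physiological baseline,
#' in mm-Hg. `avg_total_pressure` (default of the pipeline) averages the
#' mechanical pressure `-tr(sigma_tot)/3` of the mixture over the brain;
#' `avg_fluid_pressure` averages the interstitial fluid pressure `p_i`. At
#' stationarity with vigorous lymphatic drainage `p_i` sits at its drained
#' equilibrium (fractions of a Pascal), so the swelling load is carried by
#' the solid skeleton and only the total-pressure estimator reflects it.
#'
#' @param state A converged `solution_state`.
#' @param mesh The mesh (defaults to the state's).
#' @param method `"avg_total_pressure"` or `"avg_fluid_pressure"`.
#' @param warn_open Warn when applied to an open-skull state (the two-step
#'   procedure defines ICP loading on the sealed geometry).
#' @return Pressure in mm-Hg.
#' @export
icp_loading <- function(state, mesh = state$fe$mesh,
                        method = c("avg_total_pressure", "avg_fluid_pressure"),
                        warn_open = TRUE) {
  method <- match.arg(method)
  fe <- state$fe
  if (warn_open) {
    fixed_tag <- mesh$tag_names[["fixed_interface"]]
    has_open_p <- length(fe$p_fixed_vertices) > 0
    if (has_open_p)
      warning("icp_loading applied to an open-skull state; the two-step ",
              "procedure defines ICP loading on the sealed geometry")
  }
  qp <- .qp_fields(state)
  if (method == "avg_fluid_pressure") {
    pa <- sum(qp$wdet * qp$p) / sum(qp$wdet)
  } else {
    lam <- rep(state$lambda_elements, each = length(fe$quad$weights))
    Fm <- qp$F
    detF <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 6] * Fm[, 8]) -
            Fm[, 4] * (Fm[, 2] * Fm[, 9] - Fm[, 3] * Fm[, 8]) +
            Fm[, 7] * (Fm[, 2] * Fm[, 6] - Fm[, 3] * Fm[, 5])
    Je <- detF / lam^3
    # tr(sigma_s) = 3 K (Je - 1); the deviatoric part is traceless
    ptot <- -(state$Kbulk * (Je - 1)) + qp$p
    pa <- sum(qp$wdet * ptot) / sum(qp$wdet)
  }
  pa_to_mmhg(pa)
}

#' Midline shift
#'
#' Peak displacement along the sagittal-plane normal over mesh nodes lying
#' within half an element size of the mid-sagittal plane — the model's proxy
#' for the shift of the cerebral falx (which is not a distinct material in
#' this model).
#'
#' @param state A converged `solution_state`.
#' @param mesh The mesh (defaults to the state's).
#' @param band_mm Half-width of the node band around the plane; defaults to
#'   half the characteristic element size.
#' @return A list: `shift_mm` (magnitude), `signed_mm` (positive towards +x,
#'   i.e. towards the right hemisphere), `n_nodes` in the band.
#' @export
midline_shift <- function(state, mesh = state$fe$mesh, band_mm = NULL) {
  fe <- state$fe
  if (is.null(band_mm)) band_mm <- mesh$characteristic_h_mm / 2
  x1_mm <- fe$nodes[, 1] * 1000
  sel <- abs(x1_mm) <= band_mm
  if (!any(sel))
    stop("no nodes within ", band_mm, " mm of the sagittal plane; ",
         "refine the mesh or widen the band")
  ux_mm <- state$u[sel, 1] * 1000
  k <- which.max(abs(ux_mm))
  list(shift_mm = abs(ux_mm[k]), signed_mm = ux_mm[k], n_nodes = sum(sel))
}

## vectorized eigenvalues of symmetric 3x3 tensors given the 6 components
.sym3_eigenvalues <- function(s11, s22, s33, s12, s13, s23) {
  q <- (s11 + s22 + s33) / 3
  p1 <- s12^2 + s13^2 + s23^2
  p2 <- (s11 - q)^2 + (s22 - q)^2 + (s33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  pp <- ifelse(p > 0, p, 1) # p = 0: isotropic tensor, eigenvalues all q
  b11 <- (s11 - q) / pp; b22 <- (s22 - q) / pp; b33 <- (s33 - q) / pp
  b12 <- s12 / pp; b13 <- s13 / pp; b23 <- s23 / pp
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e_max <- q + 2 * p * cos(phi)
  e_min <- q + 2 * p * cos(phi + 2 * pi / 3)
  e_mid <- 3 * q - e_max - e_min
  cbind(e_min, e_mid, e_max, deparse.level = 0)
}

## solid Cauchy stress components at every quadrature point
.qp_solid_stress <- function(state) {
  fe <- state$fe
  qp <- .qp_fields(state)
  lam <- rep(state$lambda_elements, each = length(fe$quad$weights))
  Fm <- qp$F
  # be = F F^T / lambda^2 (columns of Fm: F11 F21 F31 F12 F22 F32 F13 F23 F33)
  l2 <- lam^2
  be11 <- (Fm[, 1]^2 + Fm[, 4]^2 + Fm[, 7]^2) / l2
  be22 <- (Fm[, 2]^2 + Fm[, 5]^2 + Fm[, 8]^2) / l2
  be33 <- (Fm[, 3]^2 + Fm[, 6]^2 + Fm[, 9]^2) / l2
  be12 <- (Fm[, 1] * Fm[, 2] + Fm[, 4] * Fm[, 5] + Fm[, 7] * Fm[, 8]) / l2
  be13 <- (Fm[, 1] * Fm[, 3] + Fm[, 4] * Fm[, 6] + Fm[, 7] * Fm[, 9]) / l2
  be23 <- (Fm[, 2] * Fm[, 3] + Fm[, 5] * Fm[, 6] + Fm[, 8] * Fm[, 9]) / l2
  detF <- Fm[, 1] * (Fm[, 5] * Fm[, 9] - Fm[, 6] * Fm[, 8]) -
          Fm[, 4] * (Fm[, 2] * Fm[, 9] - Fm[, 3] * Fm[, 8]) +
          Fm[, 7] * (Fm[, 2] * Fm[, 6] - Fm[, 3] * Fm[, 5])
  Je <- detF / lam^3
  mu <- state$mu; K <- state$Kbulk
  if (is.null(mu) || is.null(K))
    stop("state carries no material parameters; solve with solve_equilibrium()")
  c5 <- mu * Je^(-5 / 3)
  trb3 <- (be11 + be22 + be33) / 3
  vol <- K * (Je - 1)
  list(s11 = c5 * (be11 - trb3) + vol,
       s22 = c5 * (be22 - trb3) + vol,
       s33 = c5 * (be33 - trb3) + vol,
       s12 = c5 * be12, s13 = c5 * be13, s23 = c5 * be23,
       wdet = qp$wdet, p = qp$p)
}

#' Stress and displacement extrema
#'
#' Principal Cauchy stresses of the solid phase are evaluated at all
#' quadrature points; the maximum compressive stress is the magnitude of the
#' most negative principal value. Because the raw maximum can grow at the
#' reentrant craniectomy edge under refinement, the 99th and 95th
#' percentiles of the compressive principal stress are reported alongside.
#'
#' @param state A converged `solution_state`.
#' @param mesh The mesh (defaults to the state's).
#' @return A list: `max_compressive_stress_kPa`, `location_mm` (element
#'   centroid of the maximum), `max_displacement_mm`,
#'   `stress_percentiles_kPa` (99th and 95th).
#' @export
stress_displacement_extrema <- function(state, mesh = state$fe$mesh) {
  fe <- state$fe
  s <- .qp_solid_stress(state)
  ev <- .sym3_eigenvalues(s$s11, s$s22, s$s33, s$s12, s$s13, s$s23)
  comp <- pmax(0, -ev[, 1]) # compressive magnitude of the minimum principal
  k <- which.max(comp)
  el <- (k - 1) %/% length(fe$quad$weights) + 1
  cen <- colMeans(matrix(mesh$nodes[mesh$cells[el, ], ], 4, 3))
  qs <- stats::quantile(comp, c(0.99, 0.95), names = FALSE)
  list(max_compressive_stress_kPa = comp[k] / 1000,
       location_mm = cen,
       max_displacement_mm = 1000 * sqrt(max(rowSums(state$u^2))),
       stress_percentiles_kPa = c(p99 = qs[1] / 1000, p95 = qs[2] / 1000))
}

#' Full scalar report for a DCC state
#'
#' Bundles [herniated_volume()], [icp_loading()] (both estimators),
#' [midline_shift()] and [stress_displacement_extrema()] into one record.
#'
#' @param state A converged `solution_state`.
#' @param mesh The mesh (defaults to the state's).
#' @return A `dcc_report` list.
#' @export
dcc_report <- function(state, mesh = state$fe$mesh) {
  hv <- suppressWarnings(herniated_volume(state, mesh))
  ex <- stress_displacement_extrema(state, mesh)
  ms <- midline_shift(state, mesh)
  structure(list(
    lambda_g = state$lambda_g_achieved,
    herniated_volume_ml = hv$ml,
    herniated_volume_surface_ml = hv$ml_surface,
    volume_estimator_agreement = hv$agreement,
    icp_total_mmHg = icp_loading(state, mesh, "avg_total_pressure",
                                 warn_open = FALSE),
    icp_fluid_mmHg = icp_loading(state, mesh, "avg_fluid_pressure",
                                 warn_open = FALSE),
    midline_shift_mm = ms$shift_mm,
    midline_shift_signed_mm = ms$signed_mm,
    max_compressive_stress_kPa = ex$max_compressive_stress_kPa,
    stress_p99_kPa = ex$stress_percentiles_kPa[["p99"]],
    stress_p95_kPa = ex$stress_percentiles_kPa[["p95"]],
    max_displacement_mm = ex$max_displacement_mm), class = "dcc_report")
}

#' @export
print.dcc_report <- function(x, ...) {
  cat(sprintf("DCC report at lambda_g = %.4f\n", x$lambda_g))
  cat(sprintf("  herniated volume: %.2f ml (surface estimator %.2f ml)\n",
              x$herniated_volume_ml, x$herniated_volume_surface_ml))
  cat(sprintf("  ICP (total / fluid): %.2f / %.2g mm-Hg\n",
              x$icp_total_mmHg, x$icp_fluid_mmHg))
  cat(sprintf("  midline shift: %.2f mm; max displacement: %.2f mm\n",
              x$midline_shift_mm, x$max_displacement_mm))
  cat(sprintf("  max compressive stress: %.2f kPa (p99 %.2f, p95 %.2f)\n",
              x$max_compressive_stress_kPa, x$stress_p99_kPa, x$stress_p95_kPa))
  invisible(x)
}

#' Export solution fields to VTU
#'
#' Writes the tetrahedral mesh with point data `displacement` (cm, the unit
#' used in the clinical figures) and `p_i` (mm-Hg) at the vertices, and cell
#' data `principal_stress_min` (kPa, most negative principal solid stress
#' averaged per cell).
#'
#' @param state A converged `solution_state`.
#' @param mesh The mesh (defaults to the state's).
#' @param path Output `.vtu` path.
#' @return `invisible(path)`.
#' @export
export_fields <- function(state, mesh = state$fe$mesh, path) {
  fe <- state$fe
  nvv <- fe$nv
  disp_cm <- state$u[seq_len(nvv), , drop = FALSE] * 100 # m -> cm
  s <- .qp_solid_stress(state)
  ev <- .sym3_eigenvalues(s$s11, s$s22, s$s33, s$s12, s$s13, s$s23)
  nq <- length(fe$quad$weights)
  smin_cell <- rowsum(ev[, 1], rep(seq_len(nrow(mesh$cells)), each = nq)) / nq
  .write_vtu(mesh$nodes,
             list(list(cells = mesh$cells, type = 10L)),
             path,
             cell_data = list(principal_stress_min = as.numeric(smin_cell) / 1000,
                              region_tag = as.integer(mesh$region_tags)),
             point_data = list(displacement = disp_cm,
                               p_i = pa_to_mmhg(state$p)))
  invisible(path)
}
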