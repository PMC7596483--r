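## Two-step decompressive-craniectomy pipeline: closed-skull calibration of
## the ICP loading versus swelling, open-skull herniation simulation, and
## the scenario sweeps (opening size, injured side, shear modulus).

#' Scenario configuration
#'
#' Bundles everything one DCC simulation needs: the geometry source (either
#' parametric or an external labeled mesh), the craniectomy openings, the
#' tissue and vascular parameters, the swelling target and schedule, which
#' region is injured (swells), and solver/reporting choices.
#'
#' @param semi_axes Ellipsoid semi-axes in mm (parametric geometry).
#' @param openings List of [opening_spec()] objects.
#' @param mesh_path,mesh_format Optional external mesh (see [read_mesh()]);
#'   mutually exclusive with the parametric geometry.
#' @param h_mm Target element size for the parametric mesh.
#' @param material A [material_params()].
#' @param vascular A [vascular_params()].
#' @param lambda_g Swelling target (linear stretch ratio).
#' @param schedule Optional explicit load schedule (see [growth_field()]).
#' @param injured_regions `"whole_brain"`, `"left_hemisphere"` or
#'   `"right_hemisphere"`; the region in which swelling is prescribed.
#' @param icp_method ICP estimator used for the planning-curve abscissa.
#' @param solver A [solver_options()].
#' @param output_dir Optional directory for CSV/VTU outputs.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(semi_axes = c(80, 66, 59), openings = list(),
                            mesh_path = NULL, mesh_format = NULL, h_mm = 16,
                            material = material_params(),
                            vascular = vascular_params(),
                            lambda_g = 1.1, schedule = NULL,
                            injured_regions = c("whole_brain",
                                                "left_hemisphere",
                                                "right_hemisphere"),
                            icp_method = c("avg_total_pressure",
                                           "avg_fluid_pressure"),
                            solver = solver_options(),
                            output_dir = NULL) {
  injured_regions <- match.arg(injured_regions)
  icp_method <- match.arg(icp_method)
  if (!is.null(mesh_path) && length(openings))
    stop("give either a parametric geometry (semi_axes + openings) or ",
         "an external mesh_path, not both")
  if (inherits(openings, "opening_spec")) openings <- list(openings)
  structure(list(semi_axes = semi_axes, openings = openings,
                 mesh_path = mesh_path, mesh_format = mesh_format,
                 h_mm = h_mm, material = material, vascular = vascular,
                 lambda_g = lambda_g, schedule = schedule,
                 injured_regions = injured_regions, icp_method = icp_method,
                 solver = solver, output_dir = output_dir),
            class = "scenario_config")
}

## growth field implied by the configuration
.config_growth <- function(config) {
  lam <- if (config$injured_regions == "whole_brain") config$lambda_g
         else stats::setNames(config$lambda_g, config$injured_regions)
  growth_field(lam, schedule = config$schedule)
}

#' Build (or load) the scenario mesh
#'
#' @param config A [scenario_config()].
#' @return A `labeled_mesh`.
#' @export
scenario_mesh <- function(config) {
  if (!is.null(config$mesh_path))
    return(read_mesh(config$mesh_path, config$mesh_format))
  geom <- build_idealized_head(config$semi_axes, config$openings)
  mesh_head(geom, config$h_mm)
}

## short deterministic hash of the scenario parameters
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config[setdiff(names(config), "output_dir")], tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Closed-skull calibration step
#'
#' First step of the two-step procedure: all openings are sealed and the
#' growth stretch is ramped to its target; at every load level the
#' volume-averaged ICP loading is recorded. On a rigid sealed cavity with
#' uniform swelling the state is homogeneous, so the total-pressure ICP is
#' `Kbulk * (1 - lambda_g^-3)` regardless of the geometry.
#'
#' @param config A [scenario_config()].
#' @param mesh Optional prebuilt mesh (avoids re-meshing in sweeps).
#' @return A data frame with columns `lambda_g`, `icp_loading_mmHg` (the
#'   configured estimator), `icp_total_mmHg`, `icp_fluid_mmHg`.
#' @export
closed_skull_step <- function(config, mesh = scenario_mesh(config)) {
  growth <- .config_growth(config)
  st <- solve_equilibrium(mesh, growth, config$material, config$vascular,
                          config$solver, seal_openings = TRUE,
                          store_states = TRUE)
  states <- attr(st, "states")
  rows <- lapply(states, function(s) {
    data.frame(
      lambda_g = s$lambda_g_achieved,
      icp_total_mmHg = icp_loading(s, mesh, "avg_total_pressure",
                                   warn_open = FALSE),
      icp_fluid_mmHg = icp_loading(s, mesh, "avg_fluid_pressure",
                                   warn_open = FALSE))
  })
  out <- do.call(rbind, rows)
  if (out$lambda_g[1] > 1)
    out <- rbind(data.frame(lambda_g = 1, icp_total_mmHg = 0,
                            icp_fluid_mmHg = pa_to_mmhg(
                              starling_equilibrium_pressure(config$vascular))),
                 out)
  out$icp_loading_mmHg <- if (config$icp_method == "avg_total_pressure")
    out$icp_total_mmHg else out$icp_fluid_mmHg
  out[, c("lambda_g", "icp_loading_mmHg", "icp_total_mmHg", "icp_fluid_mmHg")]
}

#' Open-skull herniation step
#'
#' Second step: the configured openings are active, displacement is free on
#' the opening patches and the interstitial pressure is drained there
#' (`p_i = 0`); tissue bulges through the openings as swelling is ramped to
#' `lambda_g`.
#'
#' @param config A [scenario_config()].
#' @param lambda_g Target swelling for this run (defaults to the config's).
#' @param mesh Optional prebuilt mesh.
#' @param store_states Keep every load level (see [solve_equilibrium()]).
#' @return A converged `solution_state`.
#' @export
open_skull_step <- function(config, lambda_g = config$lambda_g,
                            mesh = scenario_mesh(config),
                            store_states = FALSE) {
  if (!length(config$openings) && is.null(config$mesh_path))
    stop("open_skull_step requires a geometry with at least one opening")
  cfg <- config
  cfg$lambda_g <- lambda_g
  growth <- .config_growth(cfg)
  solve_equilibrium(mesh, growth, config$material, config$vascular,
                    config$solver, store_states = store_states)
}

#' Run a full DCC scenario
#'
#' Pairs the closed-skull ICP loading at every swelling level with the
#' open-skull herniated volume and stress/displacement summaries at the same
#' level: the herniated-volume-versus-ICP planning curve. When the
#' configuration has an `output_dir`, the curve is written as CSV and each
#' level's fields as VTU.
#'
#' @param config A [scenario_config()].
#' @param mesh Optional prebuilt mesh.
#' @return A `planning_curve` data frame with columns `lambda_g`, `icp_mmHg`,
#'   `herniated_ml`, `max_comp_stress_kPa`, `max_disp_mm`,
#'   `midline_shift_mm`; metadata in attributes `opening`, `config_hash`.
#' @export
run_scenario <- function(config, mesh = scenario_mesh(config)) {
  closed <- closed_skull_step(config, mesh)
  target <- max(vapply(.config_growth(config)$lambda_g, growth_linear_stretch,
                       0, interpretation = "linear"))
  zero_row <- data.frame(lambda_g = 1, icp_mmHg = 0, herniated_ml = 0,
                         max_comp_stress_kPa = 0, max_disp_mm = 0,
                         midline_shift_mm = 0)
  if (target <= 1) {
    curve <- zero_row
  } else {
    st <- open_skull_step(config, mesh = mesh, store_states = TRUE)
    states <- attr(st, "states")
    rows <- lapply(states, function(s) {
      rep <- dcc_report(s, mesh)
      data.frame(lambda_g = s$lambda_g_achieved,
                 icp_mmHg = NA_real_,
                 herniated_ml = rep$herniated_volume_ml,
                 max_comp_stress_kPa = rep$max_compressive_stress_kPa,
                 max_disp_mm = rep$max_displacement_mm,
                 midline_shift_mm = rep$midline_shift_signed_mm)
    })
    curve <- rbind(zero_row, do.call(rbind, rows))
    curve$icp_mmHg <- stats::approx(closed$lambda_g, closed$icp_loading_mmHg,
                                    xout = curve$lambda_g, rule = 2)$y
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      for (s in states)
        export_fields(s, mesh,
                      file.path(config$output_dir,
                                sprintf("fields_lambda_%05.0f.vtu",
                                        s$lambda_g_achieved * 10000)))
    }
  }
  geom_ops <- if (!is.null(mesh$geom)) mesh$geom$openings else config$openings
  op <- if (length(geom_ops)) geom_ops[[1]] else NULL
  attr(curve, "opening") <- if (!is.null(op))
    list(kind = op$kind, area_mm2 = op$area_mm2,
         area_planar_mm2 = op$area_planar_mm2) else NULL
  attr(curve, "config_hash") <- .config_hash(config)
  class(curve) <- c("planning_curve", "data.frame")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curve, file.path(config$output_dir, "planning_curve.csv"),
                     row.names = FALSE)
  }
  curve
}

#' Injured- versus non-injured-side craniectomy study
#'
#' Swelling is prescribed in a single hemisphere and three cases are run:
#' (a) sealed skull ("control", the pre-surgical state), (b) craniectomy on
#' the side opposite the injury (contralateral), (c) craniectomy on the
#' injured side (ipsilateral). The midline shift — peak sagittal displacement
#' at the midplane — is reported for each; clinically the ipsilateral opening
#' is expected to relieve the shift below the sealed control, while the
#' contralateral opening increases it.
#'
#' @param config A [scenario_config()] whose `openings` holds one unilateral
#'   opening (its axis defines the craniectomy side) and whose
#'   `injured_regions` names the swollen hemisphere (default left).
#' @return A list with entries `control`, `contralateral`, `ipsilateral`,
#'   each containing the `dcc_report` and `midline_shift_mm`.
#' @export
hemispheric_injury_study <- function(config) {
  if (config$injured_regions == "whole_brain")
    config$injured_regions <- "left_hemisphere"
  if (length(config$openings) != 1 ||
      config$openings[[1]]$kind != "unilateral_circular")
    stop("hemispheric_injury_study needs exactly one unilateral opening")
  op <- config$openings[[1]]
  # injured side sign along the sagittal normal (+x = right hemisphere)
  inj_sign <- if (config$injured_regions == "right_hemisphere") 1 else -1
  ax <- op$axis
  ax_ipsi <- ax; ax_ipsi[1] <- inj_sign * abs(ax[1])
  ax_contra <- ax; ax_contra[1] <- -inj_sign * abs(ax[1])
  make_cfg <- function(axis) {
    cfg <- config
    o <- op; o$axis <- axis / sqrt(sum(axis^2))
    cfg$openings <- list(o)
    cfg
  }
  run_case <- function(cfg, sealed) {
    mesh <- scenario_mesh(cfg)
    growth <- .config_growth(cfg)
    st <- solve_equilibrium(mesh, growth, cfg$material, cfg$vascular,
                            cfg$solver, seal_openings = sealed)
    rep <- dcc_report(st, mesh)
    list(report = rep, midline_shift_mm = rep$midline_shift_mm,
         midline_shift_signed_mm = rep$midline_shift_signed_mm)
  }
  list(control = run_case(make_cfg(ax_ipsi), sealed = TRUE),
       contralateral = run_case(make_cfg(ax_contra), sealed = FALSE),
       ipsilateral = run_case(make_cfg(ax_ipsi), sealed = FALSE))
}

#' Shear-modulus sensitivity sweep
#'
#' Repeats the scenario for several shear moduli at fixed bulk modulus.
#' Softer tissue herniates more at the same ICP loading while the peak
#' displacement is nearly unaffected; the maximum compressive stress scales
#' roughly linearly with the shear modulus.
#'
#' @param config A [scenario_config()].
#' @param mu_values Shear moduli in Pa (default 5, 10, 20 kPa).
#' @return A named list of `planning_curve` objects, one per shear modulus.
#' @export
shear_modulus_sweep <- function(config, mu_values = c(5e3, 10e3, 20e3)) {
  mesh <- scenario_mesh(config)
  out <- lapply(mu_values, function(mu) {
    cfg <- config
    cfg$material <- material_params(mu = mu, Kbulk = config$material$Kbulk,
                                    k_hyd = config$material$k_hyd)
    run_scenario(cfg, mesh)
  })
  names(out) <- sprintf("mu_%g_kPa", mu_values / 1000)
  out
}
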