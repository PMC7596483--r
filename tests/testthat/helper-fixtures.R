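# Shared fixtures. Expensive nonlinear solves are computed once per test run
# and cached here; every consumer states what it needs through these helpers.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_semi_axes <- c(80, 66, 59)

# small head mesh with one unilateral opening (sweep resolution)
open_head_mesh <- function(radius_mm = 40, h = 16) {
  cache_get(sprintf("mesh_r%g_h%g", radius_mm, h), function() {
    geom <- build_idealized_head(
      default_semi_axes,
      list(opening_spec("unilateral_circular", radius_mm = radius_mm)))
    mesh_head(geom, h)
  })
}

sweep_solver <- function() solver_options(n_load_steps = 4)

# full-swelling open-skull solve, cached per radius
open_solve <- function(radius_mm = 40, h = 16, mu = 10e3,
                       store_states = FALSE) {
  key <- sprintf("solve_r%g_h%g_mu%g_s%d", radius_mm, h, mu, store_states)
  cache_get(key, function() {
    solve_equilibrium(open_head_mesh(radius_mm, h), growth_field(1.1),
                      material_params(mu = mu), vascular_params(),
                      sweep_solver(), store_states = store_states)
  })
}

# radius sweep of planning curves (criterion-level fixture, ~4 solves)
radius_sweep_curves <- function() {
  cache_get("radius_sweep", function() {
    lapply(c(20, 30, 40, 50), function(r) {
      cfg <- scenario_config(
        openings = list(opening_spec("unilateral_circular", radius_mm = r)),
        h_mm = 16, lambda_g = 1.1, solver = sweep_solver())
      run_scenario(cfg, mesh = open_head_mesh(r, 16))
    })
  })
}

shear_sweep_curves <- function() {
  cache_get("shear_sweep", function() {
    cfg <- scenario_config(
      openings = list(opening_spec("unilateral_circular", radius_mm = 40)),
      h_mm = 16, lambda_g = 1.1, solver = sweep_solver())
    shear_modulus_sweep(cfg, c(5e3, 10e3, 20e3))
  })
}

hemispheric_results <- function() {
  cache_get("hemispheric", function() {
    cfg <- scenario_config(
      openings = list(opening_spec("unilateral_circular", radius_mm = 40,
                                   axis = c(-1, 0, 0.35))),
      h_mm = 16, lambda_g = 1.1, injured_regions = "left_hemisphere",
      solver = sweep_solver())
    hemispheric_injury_study(cfg)
  })
}

# tiny mesh for assembly-level tests
tiny_open_mesh <- function() {
  cache_get("tiny_mesh", function() {
    geom <- build_idealized_head(
      c(40, 36, 33), list(opening_spec("unilateral_circular", radius_mm = 15)))
    mesh_head(geom, 14)
  })
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
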