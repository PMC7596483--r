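# Scalar outcomes: herniated-volume estimators, ICP estimators, midline
# shift, stress extrema, field export.

# build a solution_state with a prescribed displacement field on a mesh
synthetic_state <- function(mesh, ufun, lambda = 1, p = NULL,
                            mat = material_params()) {
  fe <- fe_setup(mesh)
  u <- ufun(fe$nodes) # nodes in meters
  if (is.null(p)) p <- numeric(fe$nv)
  structure(list(u = u, p = p, lambda_g_achieved = lambda,
                 lambda_elements = rep(lambda, nrow(fe$cells10)),
                 mu = mat$mu, Kbulk = mat$Kbulk,
                 convergence_log = NULL, fe = fe),
            class = "solution_state")
}

test_that("volumetric estimator reproduces uniform dilation exactly", {
  g <- build_idealized_head(c(40, 36, 33))
  m <- mesh_head(g, 12)
  alpha <- 0.05
  st <- synthetic_state(m, function(X) alpha * X)
  hv <- suppressWarnings(herniated_volume(st))
  V0 <- mesh_volume(m) / 1000 # ml
  expect_equal(hv$ml, ((1 + alpha)^3 - 1) * V0, tolerance = 1e-10)
})

test_that("herniated volume is zero for undeformed and confined states", {
  m <- open_head_mesh(40, 16)
  st0 <- synthetic_state(m, function(X) 0 * X)
  hv <- herniated_volume(st0)
  expect_equal(hv$ml, 0)
  expect_equal(hv$ml_surface, 0)
})

test_that("the two estimators agree on a converged open-skull state", {
  st <- open_solve(40)
  hv <- herniated_volume(st)
  expect_gt(hv$ml, 0)
  expect_lt(hv$agreement, 0.02)
})

test_that("ICP estimators convert the confined state to mm-Hg", {
  g <- build_idealized_head(default_semi_axes)
  m <- mesh_head(g, 16)
  st <- solve_equilibrium(m, growth_field(1.1), material_params(),
                          vascular_params(), solver_options(n_load_steps = 5))
  expect_equal(icp_loading(st, method = "avg_total_pressure"), 55.97,
               tolerance = 1e-3)
  expect_equal(icp_loading(st, method = "avg_fluid_pressure"), 2.2e-7,
               tolerance = 0.05)
  st1 <- solve_equilibrium(m, growth_field(1), material_params(),
                           vascular_params(), solver_options())
  expect_lt(abs(icp_loading(st1, method = "avg_total_pressure")), 1e-5)
  # warns when asked on an open-skull state
  expect_warning(icp_loading(open_solve(40)), "open-skull")
})

test_that("midline shift vanishes for symmetric states and signs correctly", {
  g <- build_idealized_head(default_semi_axes)
  m <- mesh_head(g, 16)
  st <- solve_equilibrium(m, growth_field(1.1), material_params(),
                          vascular_params(), solver_options(n_load_steps = 5))
  expect_equal(midline_shift(st)$shift_mm, 0)
  # left-hemisphere swelling in a sealed skull pushes the midline to the right
  stl <- solve_equilibrium(m, growth_field(c(left_hemisphere = 1.08)),
                           material_params(), vascular_params(),
                           solver_options(n_load_steps = 4))
  ms <- midline_shift(stl)
  expect_gt(ms$shift_mm, 0)
  expect_gt(ms$signed_mm, 0) # +x points into the right hemisphere
  # widening the band can only add candidate nodes
  expect_gte(midline_shift(stl, band_mm = 16)$n_nodes, ms$n_nodes)
  expect_error(midline_shift(st, band_mm = -1), "sagittal")
})

test_that("stress extrema report the confined plateau and percentiles", {
  g <- build_idealized_head(default_semi_axes)
  m <- mesh_head(g, 16)
  st <- solve_equilibrium(m, growth_field(1.1), material_params(),
                          vascular_params(), solver_options(n_load_steps = 5))
  ex <- stress_displacement_extrema(st)
  expect_equal(ex$max_compressive_stress_kPa, 7.4605, tolerance = 1e-4)
  # homogeneous state: percentiles equal the maximum
  expect_equal(ex$stress_percentiles_kPa[["p99"]],
               ex$max_compressive_stress_kPa, tolerance = 1e-9)
  expect_equal(ex$max_displacement_mm, 0)
  # zero growth gives all-zero extrema
  st0 <- solve_equilibrium(m, growth_field(1), material_params(),
                           vascular_params(), solver_options())
  ex0 <- stress_displacement_extrema(st0)
  expect_equal(ex0$max_compressive_stress_kPa, 0, tolerance = 1e-9)
})

test_that("field export round-trips shapes and units", {
  st <- open_solve(40)
  m <- st$fe$mesh
  p <- withr::local_tempfile(fileext = ".vtu")
  export_fields(st, m, p)
  a <- dccsim:::.read_vtu_arrays(p)
  expect_identical(nrow(a$nodes), nrow(m$nodes))
  expect_identical(length(a$cell_data$principal_stress_min), nrow(m$cells))
  disp <- a$point_data$displacement
  expect_identical(dim(disp), c(nrow(m$nodes), 3L))
  # cm in the file vs mm in the report, over the written vertex set
  max_cm <- max(sqrt(rowSums(disp^2)))
  max_mm_vertices <- 1000 * max(sqrt(rowSums(
    st$u[seq_len(st$fe$nv), , drop = FALSE]^2)))
  expect_equal(10 * max_cm, max_mm_vertices, tolerance = 1e-8)
  # lambda = 1 export is identically zero
  g <- build_idealized_head(c(40, 36, 33))
  m0 <- mesh_head(g, 12)
  st0 <- synthetic_state(m0, function(X) 0 * X)
  p0 <- withr::local_tempfile(fileext = ".vtu")
  export_fields(st0, m0, p0)
  a0 <- dccsim:::.read_vtu_arrays(p0)
  expect_equal(max(abs(a0$point_data$displacement)), 0)
  expect_equal(max(abs(a0$cell_data$principal_stress_min)), 0)
})
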