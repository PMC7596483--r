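# Discretization and nonlinear solver: quadrature exactness, consistent
# Jacobian, boundary conditions, exact discrete states, determinism.

test_that("tetrahedral quadrature integrates monomials exactly to degree 5", {
  q <- dccsim:::.tet_quadrature()
  expect_equal(sum(q$weights), 1 / 6, tolerance = 1e-14)
  for (a in 0:5) for (b in 0:(5 - a)) for (c in 0:(5 - a - b)) {
    exact <- factorial(a) * factorial(b) * factorial(c) /
      factorial(a + b + c + 3)
    num <- sum(q$weights * q$points[, 1]^a * q$points[, 2]^b * q$points[, 3]^c)
    expect_equal(num, exact, tolerance = 1e-12)
  }
})

test_that("reference state has zero residual and the confined state is exact", {
  m <- tiny_open_mesh()
  fe <- fe_setup(m, seal_openings = TRUE)
  mat <- material_params(); vasc <- vascular_params()
  p_inf <- starling_equilibrium_pressure(vasc)
  # lambda = 1, u = 0, p = p_inf: exact reference equilibrium
  r <- assemble_residual(fe, matrix(0, fe$np2, 3), rep(p_inf, fe$nv),
                         growth_field(1), mat, vasc)
  expect_lt(sqrt(sum(r$residual[r$free]^2)), 1e-12)
  # homogeneous confined growth: u = 0, p = p_inf solves the sealed problem
  lam <- 1.08
  r2 <- assemble_residual(fe, matrix(0, fe$np2, 3), rep(p_inf, fe$nv),
                          growth_field(lam), mat, vasc)
  expect_lt(sqrt(sum(r2$residual[r2$free]^2)), 1e-10)
})

test_that("assembled Jacobian matches finite differences of the residual", {
  set.seed(5)
  m <- tiny_open_mesh()
  fe <- fe_setup(m)
  mat <- material_params()
  vasc <- vascular_params(Lpl = 1e-9) # resolvable pressure scales for FD
  gr <- growth_field(1.05)
  u <- matrix(rnorm(3 * fe$np2, sd = 2e-4), fe$np2, 3, byrow = TRUE)
  p <- rnorm(fe$nv, sd = 50)
  r0 <- assemble_residual(fe, u, p, gr, mat, vasc, want_jacobian = TRUE)
  free <- r0$free
  uflat <- as.numeric(t(u))
  for (k in sample(seq_along(free), 25)) {
    gd <- free[k]
    is_u <- gd <= 3 * fe$np2
    h <- if (is_u) 1e-8 else 1e-3
    pert <- function(s) {
      uu <- uflat; pp <- p
      if (is_u) uu[gd] <- uu[gd] + s * h else
        pp[gd - 3 * fe$np2] <- pp[gd - 3 * fe$np2] + s * h
      assemble_residual(fe, matrix(uu, ncol = 3, byrow = TRUE), pp, gr,
                        mat, vasc)$residual
    }
    fd <- (pert(1) - pert(-1))[free] / (2 * h)
    expect_lt(max(abs(fd - as.numeric(r0$J[, k]))) / max(abs(fd), 1e-12),
              1e-5)
  }
})

test_that("quasistatic coupling terms are also consistently linearized", {
  set.seed(9)
  m <- tiny_open_mesh()
  fe <- fe_setup(m)
  mat <- material_params()
  vasc <- vascular_params(Lpl = 1e-9)
  lam_el <- dccsim:::.lambda_elements(fe, growth_field(1.04), 1)
  u <- rnorm(3 * fe$np2, sd = 1e-4)
  u_old <- rnorm(3 * fe$np2, sd = 1e-4)
  p <- rnorm(fe$nv, sd = 50)
  dt <- 10
  r0 <- dccsim:::.assemble(fe, u, p, lam_el, mat, vasc, 1L, TRUE, dt, u_old)
  J <- Matrix::sparseMatrix(i = r0$i, j = r0$j, x = r0$x,
                            dims = c(length(fe$free), length(fe$free)))
  for (k in sample(seq_along(fe$free), 12)) {
    gd <- fe$free[k]
    is_u <- gd <= 3 * fe$np2
    h <- if (is_u) 1e-8 else 1e-3
    up <- u; pp <- p; um <- u; pm <- p
    if (is_u) { up[gd] <- up[gd] + h; um[gd] <- um[gd] - h }
    else { pp[gd - 3 * fe$np2] <- pp[gd - 3 * fe$np2] + h
           pm[gd - 3 * fe$np2] <- pm[gd - 3 * fe$np2] - h }
    fd <- (dccsim:::.assemble(fe, up, pp, lam_el, mat, vasc, 0L, TRUE, dt,
                              u_old)$R -
           dccsim:::.assemble(fe, um, pm, lam_el, mat, vasc, 0L, TRUE, dt,
                              u_old)$R)[fe$free] / (2 * h)
    expect_lt(max(abs(fd - as.numeric(J[, k]))) / max(abs(fd), 1e-12), 1e-5)
  }
})

test_that("boundary conditions follow the facet tags", {
  # closed skull: all boundary u-dofs fixed, no pressure Dirichlet rows
  g <- build_idealized_head(default_semi_axes)
  mc <- mesh_head(g, 16)
  bc <- apply_boundary_conditions(mc)
  expect_identical(bc$n_p_dirichlet, 0L)
  expect_setequal(bc$u_fixed_vertices, sort(unique(as.vector(mc$facets))))
  # one opening: pressure fixed exactly on the patch vertices
  m1 <- open_head_mesh(40, 16)
  bc1 <- apply_boundary_conditions(m1)
  tag <- m1$tag_names[["opening_1"]]
  patch_verts <- sort(unique(as.vector(m1$facets[m1$facet_tags == tag, ])))
  expect_identical(bc1$p_fixed_vertices, patch_verts)
  # bifrontal with midline bar: both lobes drained and free
  gb <- build_idealized_head(
    default_semi_axes,
    list(opening_spec("bifrontal_midline_bar", area_mm2 = 6589)))
  mb <- mesh_head(gb, 10)
  bcb <- apply_boundary_conditions(mb)
  lobes <- mb$facet_tags %in% c(mb$tag_names[["opening_1_left"]],
                                mb$tag_names[["opening_1_right"]])
  expect_setequal(bcb$p_fixed_vertices,
                  sort(unique(as.vector(mb$facets[lobes, ]))))
  # a mesh with no fixed interface cannot constrain rigid-body motion
  m_all_open <- m1
  m_all_open$facet_tags <- rep(tag, length(m1$facet_tags))
  expect_error(apply_boundary_conditions(m_all_open), "rigid-body")
})

test_that("solver reproduces the homogeneous confined state to round-off", {
  g <- build_idealized_head(default_semi_axes)
  m <- mesh_head(g, 16)
  st <- solve_equilibrium(m, growth_field(1.1), material_params(),
                          vascular_params(), solver_options(n_load_steps = 5))
  expect_equal(max(abs(st$u)), 0)
  expect_equal(st$p, rep(starling_equilibrium_pressure(vascular_params()),
                         length(st$p)), tolerance = 1e-10)
  ex <- stress_displacement_extrema(st)
  ref <- confined_growth_reference(1.1, material_params())
  expect_equal(ex$max_compressive_stress_kPa, ref$pressure / 1000,
               tolerance = 1e-6)
  # lambda = 1 converges immediately to the zero state
  st0 <- solve_equilibrium(m, growth_field(1), material_params(),
                           vascular_params(), solver_options())
  expect_equal(max(abs(st0$u)), 0)
  expect_equal(nrow(st0$convergence_log), 1L)
})

test_that("open-skull solution bulges through the opening", {
  m <- open_head_mesh(40, 16)
  st <- open_solve(40)
  # peak displacement lies on the opening patch
  tag <- m$tag_names[["opening_1"]]
  patch_verts <- unique(as.vector(m$facets[m$facet_tags == tag, ]))
  expect_gt(max(sqrt(rowSums(st$u[patch_verts, ]^2))),
            0.95 * sqrt(max(rowSums(st$u^2))))
  # displacement vanishes on the fixed interface
  expect_equal(max(abs(st$u[st$fe$u_fixed_nodes, ])), 0)
  # herniated volume is positive
  expect_gt(suppressWarnings(herniated_volume(st))$ml, 0)
})

test_that("final state is invariant to the number of load steps", {
  geom <- build_idealized_head(
    c(40, 36, 33), list(opening_spec("unilateral_circular", radius_mm = 15)))
  m <- mesh_head(geom, 14)
  s1 <- solve_equilibrium(m, growth_field(1.1), material_params(),
                          vascular_params(), solver_options(n_load_steps = 3))
  s2 <- solve_equilibrium(m, growth_field(1.1), material_params(),
                          vascular_params(), solver_options(n_load_steps = 10))
  expect_equal(s1$u, s2$u, tolerance = 1e-6)
})

test_that("identical inputs give bit-identical convergence logs", {
  geom <- build_idealized_head(
    c(40, 36, 33), list(opening_spec("unilateral_circular", radius_mm = 15)))
  m <- mesh_head(geom, 14)
  run <- function() solve_equilibrium(m, growth_field(1.08), material_params(),
                                      vascular_params(),
                                      solver_options(n_load_steps = 3))
  a <- run(); b <- run()
  expect_identical(a$convergence_log, b$convergence_log)
  expect_identical(a$u, b$u)
})

test_that("quasistatic mode runs and approaches the stationary state", {
  geom <- build_idealized_head(
    c(40, 36, 33), list(opening_spec("unilateral_circular", radius_mm = 15)))
  m <- mesh_head(geom, 14)
  stat <- solve_equilibrium(m, growth_field(1.05), material_params(),
                            vascular_params(), solver_options(n_load_steps = 2))
  qs <- solve_equilibrium(m, growth_field(1.05), material_params(),
                          vascular_params(),
                          solver_options(n_load_steps = 2,
                                         mode = "quasistatic", dt = 1e6))
  expect_false(is.null(qs$v_s))
  # with a long time step the quasistatic solution is near equilibrium
  expect_equal(qs$u, stat$u, tolerance = 0.05)
})
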