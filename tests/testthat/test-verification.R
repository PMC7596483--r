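# Reference solutions are self-checking: each one substituted into the
# governing equation it claims to solve leaves a residual at numerical
# precision.

test_that("confined-growth reference matches the volumetric closed form", {
  mat <- material_params()
  r0 <- confined_growth_reference(1, mat)
  expect_equal(r0$stress, matrix(0, 3, 3))
  r <- confined_growth_reference(1.1, mat)
  expect_equal(r$stress, diag(30e3 * (1.1^-3 - 1), 3))
  expect_equal(r$stress[1, 1] / 1000, -7.4605, tolerance = 1e-4)
  expect_equal(r$pressure, -r$stress[1, 1])
  r2 <- confined_growth_reference(1.05, mat)
  expect_equal(r2$stress[1, 1], 30e3 * (1.05^-3 - 1), tolerance = 1e-12)
  expect_equal(r2$stress[1, 1] / 1000, -4.085, tolerance = 1e-3)
  # agrees with the constitutive module at u = 0
  sig <- solid_cauchy_stress(elastic_decomposition(diag(3), 1.07),
                             mat)
  expect_equal(confined_growth_reference(1.07, mat)$stress, sig)
})

test_that("reaction-diffusion sphere profile satisfies its ODE", {
  mat <- material_params()
  # rescaled lymphatic drainage for a resolvable boundary layer (alpha R ~ 5)
  vasc <- vascular_params(Lpl = 1.04e-12)
  R <- 0.08
  ref <- reaction_diffusion_sphere_reference(R, mat, vasc)
  expect_equal(ref$p(R), 0)
  expect_gt(ref$alpha * R, 3)
  # residual of k (1/r^2) (r^2 p')' + Q(p) on an interior grid
  r <- seq(0.1 * R, 0.95 * R, length.out = 41)
  h <- 1e-6
  p <- ref$p
  lap <- (r + h)^2 * (p(r + 2 * h) - p(r)) / (2 * h) -
         (r - h)^2 * (p(r) - p(r - 2 * h)) / (2 * h)
  lap <- lap / (2 * h * r^2)
  resid <- mat$k_hyd * lap + starling_source(p(r), vasc)
  expect_lt(max(abs(resid)) / starling_source(0, vasc), 1e-4)
  # strong drainage limit: the centre sits at the drained equilibrium
  vstrong <- vascular_params()
  refs <- reaction_diffusion_sphere_reference(R, mat, vstrong)
  expect_gt(refs$alpha * R, 1e3)
  expect_equal(refs$p(0), starling_equilibrium_pressure(vstrong),
               tolerance = 1e-10)
  # degenerate alpha = 0: Poisson closed form with constant source
  v0 <- vascular_params(Lp = 0, Lpl = 0)
  ref0 <- reaction_diffusion_sphere_reference(R, mat, v0)
  expect_equal(ref0$alpha, 0)
  expect_equal(ref0$p(R), 0)
})

test_that("oedometer reference gives the P-wave modulus", {
  mat <- material_params()
  r <- small_strain_confined_compression_reference(mat, -1e-4)
  expect_equal(r$M, 30e3 + 4 * 10e3 / 3)
  expect_equal(r$axial_stress, -(30e3 + 13.3333e3) * 1e-4, tolerance = 1e-4)
  expect_equal(small_strain_confined_compression_reference(mat, 0)$axial_stress,
               0)
  # consistency with the finite-strain stress at the same tiny strain
  eps <- -1e-5
  F <- diag(c(1, 1, 1 + eps))
  sig <- solid_cauchy_stress(elastic_decomposition(F, 1), mat)
  rr <- small_strain_confined_compression_reference(mat, eps)
  expect_equal(sig[3, 3], rr$axial_stress, tolerance = 1e-3)
  expect_equal(sig[1, 1], rr$lateral_stress, tolerance = 1e-3)
})
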