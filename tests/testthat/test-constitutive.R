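# Kinematics of growth and the constitutive laws: closed-form values,
# finite-difference stress/energy consistency, frame indifference.

test_that("growth tensor is an isotropic stretch with determinant lambda^3", {
  expect_equal(growth_tensor(1.1), diag(1.1, 3))
  expect_equal(growth_tensor(1), diag(3))
  for (lg in c(1.02, 1.05, 1.1))
    expect_equal(det(growth_tensor(lg)), lg^3)
  expect_error(growth_tensor(0.95), "resorption")
})

test_that("elastic decomposition realizes F = Fe Fg and its invariants", {
  st <- elastic_decomposition(diag(3), 1.1)
  expect_equal(st$Fe, diag(1 / 1.1, 3))
  expect_equal(st$Je, 1.1^-3)
  expect_equal(st$I1bar, 3) # pure dilation is isochorically trivial
  st2 <- elastic_decomposition(growth_tensor(1.07), 1.07)
  expect_equal(st2$Fe, diag(3))
  expect_equal(st2$Je, 1)
  expect_equal(elastic_decomposition(diag(3), 1)$Fe, diag(3))
  expect_error(elastic_decomposition(diag(c(-1, 1, 1)), 1), "positive")
  # I1bar >= 3 with equality only for pure dilation
  set.seed(42)
  for (i in 1:20) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
    if (det(F) <= 0) next
    expect_gte(elastic_decomposition(F, 1.05)$I1bar, 3 - 1e-12)
  }
})

test_that("strain energy matches its closed forms", {
  mat <- material_params()
  expect_equal(strain_energy(elastic_decomposition(growth_tensor(1.1), 1.1),
                             mat), 0)
  # fully confined swelling: W = 0.5 K (1.1^-3 - 1)^2
  st <- elastic_decomposition(diag(3), 1.1)
  expect_equal(strain_energy(st, mat), 0.5 * 30e3 * (1.1^-3 - 1)^2,
               tolerance = 1e-12)
  expect_equal(0.5 * 30e3 * (1.1^-3 - 1)^2, 927.6, tolerance = 1e-3)
  # isochoric simple shear: W ~ mu gamma^2 / 2 to leading order
  for (gam in c(1e-3, 1e-4)) {
    F <- diag(3); F[1, 2] <- gam
    W <- strain_energy(elastic_decomposition(F, 1), mat)
    expect_equal(W, 0.5 * mat$mu * gam^2, tolerance = 1e-5)
  }
})

test_that("solid Cauchy stress matches numerical differentiation of W", {
  mat <- material_params()
  # sigma = Je^-1 (dW/dFe) Fe^T via central differences on Fe
  num_stress <- function(Fe) {
    h <- 1e-6
    P <- matrix(0, 3, 3)
    for (r in 1:3) for (c in 1:3) {
      Fp <- Fe; Fp[r, c] <- Fp[r, c] + h
      Fm <- Fe; Fm[r, c] <- Fm[r, c] - h
      Wp <- strain_energy(elastic_decomposition(Fp, 1), mat)
      Wm <- strain_energy(elastic_decomposition(Fm, 1), mat)
      P[r, c] <- (Wp - Wm) / (2 * h)
    }
    (P %*% t(Fe)) / det(Fe)
  }
  set.seed(7)
  for (i in 1:5) {
    Fe <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    if (det(Fe) <= 0) next
    st <- elastic_decomposition(Fe, 1)
    sig <- solid_cauchy_stress(st, mat)
    expect_equal(sig, num_stress(Fe), tolerance = 1e-6)
    expect_equal(sig, t(sig), tolerance = 1e-9) # symmetry
  }
  # confined compression: purely volumetric, K (Je - 1) I
  st <- elastic_decomposition(diag(3), 1.1)
  expect_equal(solid_cauchy_stress(st, mat),
               diag(30e3 * (1.1^-3 - 1), 3), tolerance = 1e-12)
  expect_equal(30e3 * (1.1^-3 - 1) / 1000, -7.46, tolerance = 1e-3)
  expect_equal(solid_cauchy_stress(elastic_decomposition(diag(3), 1), mat),
               matrix(0, 3, 3))
})

test_that("solid stress is frame indifferent", {
  mat <- material_params()
  set.seed(11)
  Fe <- diag(3) + matrix(rnorm(9, sd = 0.08), 3, 3)
  sig <- solid_cauchy_stress(elastic_decomposition(Fe, 1), mat)
  for (i in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, pi))
    sigR <- solid_cauchy_stress(elastic_decomposition(R %*% Fe, 1), mat)
    expect_equal(sigR, R %*% sig %*% t(R), tolerance = 1e-10)
  }
})

test_that("small-strain limit recovers the Lame moduli", {
  mat <- material_params()
  set.seed(3)
  eps <- matrix(rnorm(9), 3, 3) * 1e-7
  eps <- (eps + t(eps)) / 2
  sig <- solid_cauchy_stress(elastic_decomposition(diag(3) + eps, 1), mat)
  # K tr(eps) I + 2 mu dev(eps) == lambda_Lame tr(eps) I + 2 mu eps
  sig_lin <- mat$Kbulk * sum(diag(eps)) * diag(3) +
    2 * mat$mu * (eps - diag(sum(diag(eps)) / 3, 3))
  expect_equal(sig, sig_lin, tolerance = 1e-5)
})

test_that("confined-growth stress is linear in the bulk modulus", {
  s <- vapply(c(10e3, 20e3, 40e3), function(K) {
    mat <- material_params(Kbulk = K)
    solid_cauchy_stress(elastic_decomposition(diag(3), 1.08), mat)[1, 1]
  }, 0)
  expect_equal(s[2] / s[1], 2, tolerance = 1e-12)
  expect_equal(s[3] / s[2], 2, tolerance = 1e-12)
})

test_that("fluid and total stress follow the poromechanics sign convention", {
  st <- elastic_decomposition(diag(3), 1)
  mat <- material_params()
  expect_equal(total_stress(st, 0, mat), matrix(0, 3, 3))
  expect_equal(fluid_stress(1000), diag(-1000, 3))
  expect_equal(-sum(diag(total_stress(st, 1000, mat))) / 3, 1000)
  # confined swelling alone reads ~56 mm-Hg of total pressure
  stc <- elastic_decomposition(diag(3), 1.1)
  icp <- -sum(diag(total_stress(stc, 0, mat))) / 3
  expect_equal(pa_to_mmhg(icp), 55.96, tolerance = 1e-3)
})

test_that("Starling exchange is linear with the expected root and rate", {
  vasc <- vascular_params()
  expect_equal(starling_source(0, vasc), 2.7e-12 * 7000 * 4000)
  p_inf <- starling_equilibrium_pressure(vasc)
  expect_equal(p_inf, 2.88e-5, tolerance = 1e-3)
  expect_equal(starling_source(p_inf, vasc), 0)
  # negative slope
  expect_lt(starling_source(100, vasc), starling_source(0, vasc))
  # degenerate: both conductivities zero
  v0 <- vascular_params(Lp = 0, Lpl = 0)
  expect_equal(starling_source(123, v0), 0)
  expect_equal(starling_equilibrium_pressure(v0), 0)
})

test_that("Darcy flux is linear in the gradient and gated vf recovery works", {
  mat <- material_params()
  expect_equal(darcy_relative_flux(c(0, 0, 0), mat), c(0, 0, 0))
  expect_equal(darcy_relative_flux(c(1000, 0, 0), mat),
               c(-6.7e-9, 0, 0))
  g <- c(3, -2, 7) * 100
  expect_equal(darcy_relative_flux(2 * g, mat),
               2 * darcy_relative_flux(g, mat))
  expect_error(darcy_relative_flux(g, mat, vascular_params(), recover_vf = TRUE),
               "phi_f")
  out <- darcy_relative_flux(g, mat, vascular_params(phi_f = 0.2),
                             recover_vf = TRUE)
  expect_equal(out$v_f, out$flux / 0.2)
})
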