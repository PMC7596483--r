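#' Confined-growth reference state
#'
#' Closed rigid cavity, uniform swelling: with the whole boundary fixed the
#' exact solution is zero displacement, so `Fe = lambda_g^-1 * I` everywhere
#' and the solid stress is the homogeneous volumetric state
#' `sigma_s = Kbulk * (lambda_g^-3 - 1) * I` (compressive for any swelling).
#' Used as an analytic oracle for the nonlinear solver on any closed geometry.
#'
#' @param lambda_g Growth stretch ratio, `>= 1`.
#' @param mat A [material_params()] object.
#' @return A list with `stress` (3x3, Pa), `pressure` (the total-stress ICP
#'   `-tr(sigma)/3` in Pa) and `Je`.
#' @export
confined_growth_reference <- function(lambda_g, mat) {
  stopifnot(lambda_g >= 1, inherits(mat, "material_params"))
  Je <- lambda_g^-3
  s <- mat$Kbulk * (Je - 1)
  list(stress = diag(s, 3), pressure = -s, Je = Je)
}

#' Reaction-diffusion sphere reference profile
#'
#' Stationary interstitial pressure in a sphere of radius `R` with the
#' Starling exchange as a linear reaction term and `p_i = 0` on the surface:
#' `-k lap(p) = Q(p)` has the closed-form radial solution
#' `p(r) = p_inf * (1 - R sinh(alpha r) / (r sinh(alpha R)))` with
#' `alpha^2 = (Lp SV + Lpl SlVl) / k`. In the degenerate `alpha = 0` limit
#' (no drainage term, constant source `q0 = Lp SV pv`) the Poisson solution
#' `p(r) = q0 (R^2 - r^2) / (6 k)` is returned instead.
#'
#' @param radius_m Sphere radius, m.
#' @param mat A [material_params()] object (supplies `k_hyd`).
#' @param vasc A [vascular_params()] object.
#' @return A list with the vectorized evaluator `p(r)`, `alpha`, `p_inf`
#'   and `radius_m`.
#' @export
reaction_diffusion_sphere_reference <- function(radius_m, mat, vasc) {
  stopifnot(radius_m > 0, inherits(mat, "material_params"),
            inherits(vasc, "vascular_params"))
  k <- mat$k_hyd
  beta <- vasc$Lp * vasc$SV + vasc$Lpl * vasc$SlVl
  if (beta > 0) {
    alpha <- sqrt(beta / k)
    p_inf <- starling_equilibrium_pressure(vasc)
    p_fun <- function(r) {
      r <- as.numeric(r)
      out <- p_inf * (1 - radius_m * sinh(alpha * r) / (r * sinh(alpha * radius_m)))
      # r -> 0 limit: p_inf * (1 - alpha R / sinh(alpha R))
      out[r == 0] <- p_inf * (1 - alpha * radius_m / sinh(alpha * radius_m))
      out
    }
  } else {
    alpha <- 0
    q0 <- vasc$Lp * vasc$SV * vasc$pv + vasc$Lpl * vasc$SlVl * vasc$pl
    p_inf <- Inf # no drained equilibrium; pressure grows with domain size
    p_fun <- function(r) q0 * (radius_m^2 - as.numeric(r)^2) / (6 * k)
  }
  list(p = p_fun, alpha = alpha, p_inf = p_inf, radius_m = radius_m)
}

#' Small-strain confined (oedometer) compression reference
#'
#' Uniaxial strain with lateral confinement: to first order in the applied
#' strain the axial stress is `(Kbulk + 4 mu / 3) * strain`, the standard
#' P-wave (oedometer) modulus. Used to verify that the finite-strain solver
#' linearizes to the correct small-strain moduli.
#'
#' @param mat A [material_params()] object.
#' @param applied_strain Axial engineering strain, `|strain| <= 1e-4`.
#' @return A list with `axial_stress` (Pa), `lateral_stress` (Pa) and the
#'   oedometer modulus `M`.
#' @export
small_strain_confined_compression_reference <- function(mat, applied_strain) {
  stopifnot(inherits(mat, "material_params"), abs(applied_strain) <= 1e-4)
  M <- mat$Kbulk + 4 * mat$mu / 3
  lam <- mat$Kbulk - 2 * mat$mu / 3
  list(axial_stress = M * applied_strain,
       lateral_stress = lam * applied_strain,
       M = M)
}
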