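#' Brain tissue material parameters
#'
#' Constitutive coefficients of the solid skeleton and its hydraulic
#' conductivity, all in SI units. Defaults are the homogeneous adult-brain
#' values used throughout the package: shear modulus 10 kPa, bulk modulus
#' 30 kPa, tissue hydraulic conductivity 6.7e-12 m^2/(Pa s).
#'
#' @param mu Shear modulus of the solid phase, Pa.
#' @param Kbulk Bulk modulus of the solid phase, Pa.
#' @param k_hyd Hydraulic conductivity of the tissue, m^2 Pa^-1 s^-1.
#' @return An object of class `material_params`.
#' @export
material_params <- function(mu = 10e3, Kbulk = 30e3, k_hyd = 6.7e-12) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(Kbulk), length(Kbulk) == 1L, is.finite(Kbulk),
            is.numeric(k_hyd), length(k_hyd) == 1L, is.finite(k_hyd))
  if (mu <= 0 || Kbulk <= 0 || k_hyd <= 0)
    stop("material parameters must be strictly positive")
  if (Kbulk < (2 / 3) * mu)
    stop("Kbulk must be >= 2*mu/3 for a positive-definite small-strain stiffness")
  structure(list(mu = mu, Kbulk = Kbulk, k_hyd = k_hyd),
            class = "material_params")
}

#' Vascular and lymphatic exchange parameters
#'
#' Coefficients of the Starling source term describing fluid exchange between
#' the interstitium and the blood / lymphatic microvasculature. Wall
#' conductivities carry the standard Starling dimension m Pa^-1 s^-1 so that
#' the volumetric exchange rate Q has units s^-1; magnitudes follow the
#' brain-tissue literature values used by the package defaults.
#'
#' @param Lp Vascular wall hydraulic conductivity, m Pa^-1 s^-1.
#' @param SV Vascular density S/V, m^-1.
#' @param pv Microvascular (blood) pressure, Pa.
#' @param Lpl Lymphatic wall hydraulic conductivity, m Pa^-1 s^-1.
#' @param SlVl Lymphatic density Sl/Vl, m^-1.
#' @param pl Lymphatic pressure, Pa.
#' @param phi_f Interstitial fluid volume fraction in `[0, 1)`; optional, used
#'   only to recover the intrinsic fluid velocity from the Darcy flux.
#' @return An object of class `vascular_params`.
#' @export
vascular_params <- function(Lp = 2.7e-12, SV = 7000, pv = 4e3,
                            Lpl = 3.75e-4, SlVl = 7000, pl = 0,
                            phi_f = NULL) {
  if (Lp < 0 || Lpl < 0 || SV < 0 || SlVl < 0)
    stop("conductivities and vessel densities must be non-negative")
  if (!is.null(phi_f)) {
    stopifnot(is.numeric(phi_f), length(phi_f) == 1L)
    if (phi_f < 0 || phi_f >= 1) stop("phi_f must lie in [0, 1)")
  }
  structure(list(Lp = Lp, SV = SV, pv = pv, Lpl = Lpl, SlVl = SlVl, pl = pl,
                 phi_f = phi_f),
            class = "vascular_params")
}

#' Swelling (growth) field
#'
#' The degree of brain swelling is imposed as an isotropic inelastic stretch
#' `lambda_g >= 1`, either uniformly over the whole brain or per hemisphere.
#' The load schedule ramps `lambda_g` from 1 to the target; solvers step
#' through it incrementally.
#'
#' @param lambda_g Either a single target stretch ratio (whole-brain swelling)
#'   or a named vector with entries `left_hemisphere` and/or `right_hemisphere`
#'   (unset hemispheres stay at 1).
#' @param schedule Optional strictly increasing vector of load levels in
#'   `(1, ...]` ending at 1 + the largest swelling increment; each level `s`
#'   scales every regional increment as `1 + (s - 1)/(max - 1) * (target - 1)`.
#'   When `NULL` a uniform ramp is built from the solver's `n_load_steps`.
#' @param interpretation `"linear"` (default): `lambda_g` is the linear stretch
#'   ratio, so 1.1 produces 33.1\% volumetric swelling. `"volumetric"`:
#'   `lambda_g` is reinterpreted as a volume ratio and the linear stretch used
#'   internally is `lambda_g^(1/3)`.
#' @return An object of class `growth_field`.
#' @export
growth_field <- function(lambda_g = 1.1, schedule = NULL,
                         interpretation = c("linear", "volumetric")) {
  interpretation <- match.arg(interpretation)
  if (is.null(names(lambda_g))) {
    stopifnot(length(lambda_g) == 1L)
    lambda_g <- c(whole_brain = unname(lambda_g))
  } else {
    bad <- setdiff(names(lambda_g),
                   c("whole_brain", "left_hemisphere", "right_hemisphere"))
    if (length(bad))
      stop("unknown region name(s): ", paste(bad, collapse = ", "))
  }
  if (any(lambda_g < 1))
    stop("lambda_g must be >= 1 in every region (resorption is not modelled)")
  target <- max(lambda_g)
  if (!is.null(schedule)) {
    stopifnot(is.numeric(schedule), all(diff(c(1, schedule)) > 0))
    if (target > 1 && abs(schedule[length(schedule)] - target) > 1e-12)
      stop("schedule must end at the target lambda_g (", target, ")")
  }
  structure(list(lambda_g = lambda_g, schedule = schedule,
                 interpretation = interpretation),
            class = "growth_field")
}

## linear stretch actually applied for a growth field at a schedule level
growth_linear_stretch <- function(lambda_g, interpretation = "linear") {
  if (interpretation == "volumetric") lambda_g^(1 / 3) else lambda_g
}

#' Isotropic growth tensor
#'
#' Swelling is modelled as the inelastic deformation gradient
#' `Fg = lambda_g * I`: an isotropic stretch of the tissue's stress-free
#' configuration. Its determinant `lambda_g^3` is the local volumetric gain.
#'
#' @param lambda_g Tissue stretch ratio, `>= 1`.
#' @return A 3x3 matrix `lambda_g * I`.
#' @export
growth_tensor <- function(lambda_g) {
  stopifnot(is.numeric(lambda_g), length(lambda_g) == 1L, is.finite(lambda_g))
  if (lambda_g < 1)
    stop("lambda_g must be >= 1 (resorption is not modelled)")
  diag(lambda_g, 3)
}

#' Multiplicative elastic/growth decomposition
#'
#' Splits a total deformation gradient `F` into growth and elastic parts via
#' `F = Fe . Fg` with `Fg = lambda_g * I`, and records the elastic volume
#' ratio `Je = det(Fe)` and the isochoric first invariant
#' `I1bar = Je^(-2/3) tr(Fe^T Fe)`. Only `Fe` carries stress.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param lambda_g Growth stretch ratio, `>= 1`.
#' @return An object of class `deformation_state` with fields `F`, `Fg`, `Fe`,
#'   `Je`, `I1bar`, `lambda_g`.
#' @export
elastic_decomposition <- function(F, lambda_g = 1) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("det(F) must be positive (element inversion)")
  if (lambda_g < 1) stop("lambda_g must be >= 1")
  Fe <- F / lambda_g
  Je <- J / lambda_g^3
  I1bar <- Je^(-2 / 3) * sum(Fe * Fe)
  structure(list(F = F, Fg = growth_tensor(lambda_g), Fe = Fe, Je = Je,
                 I1bar = I1bar, lambda_g = lambda_g),
            class = "deformation_state")
}

#' Strain energy density
#'
#' Modified neo-Hookean energy of the elastic part of the deformation, per
#' unit intermediate (grown, stress-free) volume:
#' `W = 0.5 * (mu * (I1bar - 3) + Kbulk * (Je - 1)^2)`.
#' The deviatoric term uses the isochoric invariant, so W vanishes exactly
#' when `Fe` is a rotation and the two terms decouple shear from volume
#' change.
#'
#' @param state A `deformation_state` from [elastic_decomposition()].
#' @param mat A `material_params` object.
#' @return Energy density in Pa.
#' @export
strain_energy <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"), inherits(mat, "material_params"))
  0.5 * (mat$mu * (state$I1bar - 3) + mat$Kbulk * (state$Je - 1)^2)
}

#' Cauchy stress of the solid phase
#'
#' Derived from the strain energy via `sigma_s = Je^-1 Fe . dW/dFe^T`. For the
#' isochoric-split neo-Hookean energy this evaluates to
#' `mu * Je^(-5/3) * dev(be) + Kbulk * (Je - 1) * I` with `be = Fe Fe^T`:
#' a purely deviatoric shear response plus a volumetric pressure
#' `Kbulk * (Je - 1)`.
#'
#' @inheritParams strain_energy
#' @return A symmetric 3x3 Cauchy stress tensor, Pa.
#' @export
solid_cauchy_stress <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"), inherits(mat, "material_params"))
  be <- state$Fe %*% t(state$Fe)
  Je <- state$Je
  dev_be <- be - diag(sum(diag(be)) / 3, 3)
  mat$mu * Je^(-5 / 3) * dev_be + diag(mat$Kbulk * (Je - 1), 3)
}

#' Fluid phase stress
#'
#' The interstitial fluid contributes an isotropic stress `-p_i * I`:
#' positive interstitial pressure loads the solid compressively (standard
#' poromechanics sign convention).
#'
#' @param p_i Interstitial fluid pressure, Pa.
#' @return A 3x3 tensor, Pa.
#' @export
fluid_stress <- function(p_i) {
  stopifnot(is.numeric(p_i), length(p_i) == 1L)
  diag(-p_i, 3)
}

#' Total (mixture) Cauchy stress
#'
#' Sum of the solid skeleton stress and the fluid stress; the momentum balance
#' of the biphasic mixture is `div(sigma_s + sigma_f) = 0`.
#'
#' @inheritParams strain_energy
#' @param p_i Interstitial fluid pressure, Pa.
#' @return A symmetric 3x3 tensor, Pa.
#' @export
total_stress <- function(state, p_i, mat) {
  solid_cauchy_stress(state, mat) + fluid_stress(p_i)
}

#' Starling fluid exchange source
#'
#' Net volumetric rate of fluid entering the interstitium from the blood
#' microvasculature minus drainage into lymphatics:
#' `Q = Lp*(S/V)*(pv - p_i) - Lpl*(Sl/Vl)*(p_i - pl)`, in s^-1. Q is linear
#' in `p_i` with negative slope; its root is the drained equilibrium pressure
#' returned by [starling_equilibrium_pressure()].
#'
#' @param p_i Interstitial fluid pressure, Pa (vectorized).
#' @param vasc A `vascular_params` object.
#' @return Volumetric exchange rate, s^-1.
#' @export
starling_source <- function(p_i, vasc) {
  stopifnot(inherits(vasc, "vascular_params"))
  vasc$Lp * vasc$SV * (vasc$pv - p_i) - vasc$Lpl * vasc$SlVl * (p_i - vasc$pl)
}

#' Drained equilibrium pressure of the Starling exchange
#'
#' The pressure at which vascular filtration balances lymphatic drainage,
#' `p_inf = (Lp*SV*pv + Lpl*SlVl*pl) / (Lp*SV + Lpl*SlVl)`. With both
#' conductivities zero the exchange is identically zero and `p_inf` is
#' returned as 0 by convention.
#'
#' @param vasc A `vascular_params` object.
#' @return Equilibrium pressure, Pa.
#' @export
starling_equilibrium_pressure <- function(vasc) {
  stopifnot(inherits(vasc, "vascular_params"))
  denom <- vasc$Lp * vasc$SV + vasc$Lpl * vasc$SlVl
  if (denom == 0) return(0)
  (vasc$Lp * vasc$SV * vasc$pv + vasc$Lpl * vasc$SlVl * vasc$pl) / denom
}

#' Darcy relative flux
#'
#' Flux of interstitial fluid relative to the solid skeleton,
#' `phi_f * (v_f - v_s) = -k_hyd * grad(p_i)`. The intrinsic fluid velocity
#' `v_f` can optionally be recovered by dividing by `phi_f`, which must then
#' be set in `vasc`.
#'
#' @param grad_p Pressure gradient, Pa m^-1 (length-3 vector).
#' @param mat A `material_params` object (supplies `k_hyd`).
#' @param vasc Optional `vascular_params`; required only for `recover_vf`.
#' @param recover_vf If `TRUE`, also return the intrinsic fluid velocity
#'   `v_s + flux / phi_f` component (with `v_s = 0`).
#' @return The relative flux vector in m/s, or a list with `flux` and `v_f`
#'   when `recover_vf = TRUE`.
#' @export
darcy_relative_flux <- function(grad_p, mat, vasc = NULL, recover_vf = FALSE) {
  stopifnot(inherits(mat, "material_params"), length(grad_p) == 3L)
  flux <- -mat$k_hyd * as.numeric(grad_p)
  if (!recover_vf) return(flux)
  if (is.null(vasc) || is.null(vasc$phi_f) || vasc$phi_f <= 0)
    stop("fluid-velocity recovery requires vascular_params with phi_f set")
  list(flux = flux, v_f = flux / vasc$phi_f)
}

## unit conversion used at all reporting boundaries
PA_PER_MMHG <- 133.322

#' Convert pressure between Pa and mm-Hg
#'
#' @param x Pressure value(s).
#' @return Converted value(s); 1 mm-Hg = 133.322 Pa.
#' @export
pa_to_mmhg <- function(x) x / PA_PER_MMHG

#' @rdname pa_to_mmhg
#' @export
mmhg_to_pa <- function(x) x * PA_PER_MMHG
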