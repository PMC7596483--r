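---
title: "Biphasic growth-driven modelling of decompressive craniectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic growth-driven modelling of decompressive craniectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical question and the model

Decompressive craniectomy (DCC) removes a portion of the skull so that a
swollen, post-traumatic brain can herniate outward instead of compressing
itself against a rigid cranium. The planning question is quantitative: for a
given opening size and location, how much tissue will herniate at a given
pre-surgical intracranial pressure (ICP), and what stresses does the tissue
experience? `dccsim` answers this with a finite-strain, biphasic
finite-element model of the brain inside a rigid skull.

### Balance laws

The tissue is a mixture of a solid skeleton (volume fraction $\varphi^s$)
saturated by interstitial fluid ($\varphi^f = 1 - \varphi^s$). Mass balance
of the two phases, with Darcy flow
$\varphi^f(\mathbf v^f - \mathbf v^s) = -k\,\nabla p_i$ for the relative
fluid motion, combines into a single pressure equation

$$-k\,\nabla^2 p_i \;=\; Q(p_i) \;-\; \nabla\cdot\mathbf v^s ,$$

where $p_i$ is the interstitial fluid pressure and the Starling source

$$Q(p_i) = L_p \tfrac{S}{V}\,(p_v - p_i)\;-\;L_{pl}\tfrac{S_l}{V_l}\,(p_i - p_l)$$

exchanges fluid with the blood microvasculature and the lymphatics.
Momentum balance of the mixture is
$\nabla\cdot(\boldsymbol\sigma^s + \boldsymbol\sigma^f) = 0$ with the fluid
contribution implemented as $\boldsymbol\sigma^f = -p_i\mathbf I$, the
standard poromechanics convention in which positive interstitial pressure
loads the skeleton compressively. (The sign is a deliberate design choice:
the alternative convention makes interstitial pressure *tensile* on the
solid, which is unphysical here; with the default drainage parameters
$p_i \approx 0$ at stationarity and the choice is numerically immaterial.)

### Swelling as multiplicative growth

Edema is modelled as isotropic inelastic growth: the deformation gradient
splits multiplicatively, $\mathbf F = \mathbf F_e \mathbf F_g$ with
$\mathbf F_g = \lambda_g \mathbf I$, and only the elastic part
$\mathbf F_e$ carries stress. A swelling of 10% means $\lambda_g = 1.1$
(linear stretch, i.e. 33.1% volume gain); a `"volumetric"` interpretation
flag is available for sensitivity studies because the two readings differ by
a factor of three in volume. The solid is modified neo-Hookean,

$$W = \tfrac12\left[\mu(\bar I_1 - 3) + K (J_e - 1)^2\right],
\qquad \bar I_1 = J_e^{-2/3}\,\mathrm{tr}(\mathbf F_e^T\mathbf F_e),$$

with the isochoric invariant so that the $\mu$-term is purely deviatoric and
$\mu$, $K$ are the small-strain shear and bulk moduli. The Cauchy stress is
$\boldsymbol\sigma^s = J_e^{-1}\,\partial W/\partial \mathbf F_e\cdot
\mathbf F_e^T = \mu J_e^{-5/3}\,\mathrm{dev}(\mathbf b_e) + K(J_e-1)\mathbf I$.
Viscoelasticity is deliberately absent: DCC acts over minutes to hours,
long compared to brain tissue's stress-relaxation times.

### Parameters

| parameter | symbol | default | units |
|---|---|---|---|
| shear modulus | $\mu$ | 10e3 | Pa |
| bulk modulus | $K$ | 30e3 | Pa |
| tissue hydraulic conductivity | $k$ | 6.7e-12 | m² Pa⁻¹ s⁻¹ |
| vascular wall conductivity | $L_p$ | 2.7e-12 | m Pa⁻¹ s⁻¹ |
| vascular density | $S/V$ | 7000 | m⁻¹ |
| microvascular pressure | $p_v$ | 4e3 | Pa |
| lymphatic wall conductivity | $L_{pl}$ | 3.75e-4 | m Pa⁻¹ s⁻¹ |
| lymphatic density | $S_l/V_l$ | 7000 | m⁻¹ |
| lymphatic pressure | $p_l$ | 0 | Pa |

The defaults are homogeneous adult-brain literature values. Wall
conductivities are dimensioned m Pa⁻¹ s⁻¹ (so $Q$ is a volumetric rate,
s⁻¹); their magnitudes follow the brain-tissue modelling literature, which
sometimes prints them with the same units as the tissue conductivity. The
fluid volume fraction $\varphi^f$ has no default: it is only needed to
recover the intrinsic fluid velocity from the Darcy flux and is left unset
otherwise.

A consequence of these defaults worth knowing: the pressure equation is
extremely reaction-dominated. Its boundary-layer width is
$\sqrt{k/(L_p S/V + L_{pl} S_l/V_l)} \approx 1.6\,\mu\mathrm m$, so at
stationarity $p_i$ sits at its drained equilibrium
$p_\infty \approx 2.9\times10^{-5}$ Pa everywhere except in layers far below
mesh resolution. Reaction-dominated problems of this type are not
oscillatory, so no stabilization is used; verification of the pressure
solver instead rescales the lymphatic conductivity to make the layer
resolvable (see below). The practical consequence is that the swelling load
is carried by the solid skeleton, and the meaningful ICP estimator is the
mechanical one (next section).

## The two-step DCC procedure

1. **Closed-skull calibration.** All openings are sealed, the skull
   interface is rigid (`u = 0` everywhere on the boundary), and
   $\lambda_g$ is ramped from 1 to its target. The homogeneous state
   $\mathbf u \equiv 0$, $\mathbf F_e = \lambda_g^{-1}\mathbf I$ is then the
   *exact* solution, with
   $\boldsymbol\sigma^s = K(\lambda_g^{-3}-1)\mathbf I$; the volume-averaged
   ICP loading at each level maps swelling to pressure. At
   $\lambda_g = 1.1$ with the defaults this is 7.46 kPa = 55.96 mm-Hg.
   Two estimators are provided: `avg_total_pressure`
   ($-\mathrm{tr}(\boldsymbol\sigma_{tot})/3$, the default) and
   `avg_fluid_pressure` ($p_i$, which at stationarity is $\approx p_\infty
   \approx 0$ and therefore cannot represent the loading). ICP loading is
   reported relative to the physiological baseline (7–15 mm-Hg), which the
   clinician adds back.

2. **Open-skull herniation.** The same mesh with the opening facets active:
   traction-free displacement and $p_i = 0$ (free drainage) on the patches,
   rigid elsewhere. The converged state at each $\lambda_g$ level yields the
   herniated volume, midline shift and stress summaries, which are paired
   with the closed-skull ICP at the same level to form the planning curve.

Whether the original two-step studies sealed the same mesh or used a
distinct closed geometry is not documented; `dccsim` seals the same mesh,
which eliminates any meshing difference between the steps (and, because the
sealed solution is homogeneous, the calibration is in fact
geometry-independent).

## Synthetic geometry

Subject-specific image-derived geometry is out of scope; the generator
builds an idealized head at adult scale:

* The cavity is a triaxial ellipsoid, default semi-axes 80 × 66 × 59 mm
  (≈ 1.3 l), origin at the centroid; +x points into the right hemisphere,
  +y anterior, +z superior.
* A **unilateral circular** opening of radius $r$ is the surface patch cut
  by a cylinder of radius $r$ along the surface normal through the opening
  centre — a circular bone cut. Its planar cross-sectional area $\pi r^2$
  (the number quoted clinically) is reported alongside the true curved patch
  area, which is 3–40% larger depending on $r$.
* **Bifrontal** openings (optionally split by a retained midline bone bar,
  default 25 mm wide) are elliptical angular sectors about an
  anterior-superior axis; when a total area is requested the angular extents
  are found by a 1-D root search to within 1%.
* Meshing sweeps an icosphere surface radially into prism layers, each split
  into three tetrahedra with an index-ordered diagonal rule that keeps
  neighbouring prisms conforming; the unit ball is then scaled onto the
  semi-axes. Mesh volume converges to the analytic ellipsoid volume at
  roughly fourth-order in the subdivision level (0.9% low at the default
  resolution, h = 8 mm).

What the generator does *not* emulate: gyral folding, the falx and
tentorium, ventricles, gray/white heterogeneity, skull thickness, and true
craniectomy edge geometry (the rim here is a sharp rigid edge). Passing
tests on this geometry demonstrate correctness of the mechanics and the
orderings the model predicts, not subject-specific accuracy.

## Discretization and solver

* Mixed Taylor–Hood-style pair: quadratic Lagrange displacements, linear
  Lagrange pressure, on shared tetrahedra. Assembly is total-Lagrangian:
  the momentum residual uses the first Piola transform of the total stress
  (with the growth factor $\det\mathbf F_g = \lambda_g^3$ converting energy
  to the reference volume), and the Darcy operator is pulled back as
  $J\mathbf F^{-1}k\mathbf F^{-T}$.
* Quadrature: a conical-product rule (3×3×3 Gauss–Jacobi, 27 points,
  exact to total degree 5) built by Golub–Welsch at setup and verified
  against monomial integrals in the test suite.
* Newton with incremental load stepping (default 10 uniform increments of
  $\lambda_g$) and a backtracking line search (halving, at most 8 halvings).
  The default convergence tolerances are 1e-8 relative / 1e-10 absolute on
  the residual norm.
* Each Newton step factors the two *diagonal* blocks of the exact Jacobian —
  the symmetric momentum tangent (supernodal Cholesky, with a small
  Levenberg-style diagonal shift as fallback for indefinite states) and the
  symmetric positive-definite pressure block — in a block Gauss–Seidel
  arrangement. The Darcy/Starling coupling enters through the residual, on
  which convergence is always measured, so converged states satisfy the
  fully coupled equations; with the default parameters the coupling is
  many orders of magnitude below the block terms and the iteration count is
  indistinguishable from full Newton. The *fully coupled* consistent
  Jacobian (including both off-diagonal blocks) is assembled by
  `assemble_residual(want_jacobian = TRUE)` and is verified against finite
  differences of the residual to 1e-5 relative in the tests.
* Stationary mode is the default ($\mathbf v^s = 0$; the model targets the
  post-DCC equilibrium). A quasistatic mode (backward-Euler
  $\mathbf v^s = \Delta\mathbf u/\Delta t$ coupling) is provided for
  transient studies and is smoke-tested only.
* Everything is deterministic: direct factorizations, no randomized
  components; identical inputs reproduce convergence logs bit for bit.

### Verification oracles

* **Confined growth**: on any closed geometry the homogeneous state is an
  exact discrete solution; the solver reproduces $\mathbf u = 0$ and
  $\boldsymbol\sigma^s = K(\lambda_g^{-3}-1)\mathbf I$ to round-off.
* **Reaction–diffusion sphere**: with $p_i = 0$ on the surface of a sphere
  of radius $R$ and the displacement frozen, the pressure has the closed
  form $p(r) = p_\infty\left[1 - \frac{R\sinh(\alpha r)}{r\sinh(\alpha R)}
  \right]$, $\alpha^2 = (L_pS/V + L_{pl}S_l/V_l)/k$. The test rescales
  $L_{pl}$ so that $\alpha R = 5$ (a resolvable layer) and uses a radially
  refined mesh (icosphere subdivision 2, 20 radial layers, ~18.5k
  tetrahedra); the FE field matches the profile to 0.8% in relative L2.
  The paper-default parameters are separately checked for the
  $p_i \to p_\infty$ plateau.
* **Oedometer limit**: the finite-strain stress linearizes to the P-wave
  modulus $K + 4\mu/3$ under confined uniaxial strain.

## Outcome measures

* **Herniated volume**: primary estimator $\int(\det\mathbf F - 1)\,dV_0$
  over the reference brain; secondary estimator, the flux volume enclosed
  between the deformed and undeformed opening patches (exact for a fixed
  rim by the divergence theorem). The two agree within 2% on resolved
  meshes and their disagreement is attached to reports as a mesh-quality
  warning.
* **Midline shift**: peak sagittal-normal displacement over nodes within
  half an element size of the mid-sagittal plane — a falx proxy, since the
  falx is not a distinct material.
* **Stress extrema**: principal Cauchy stresses of the solid phase at
  quadrature points; the "maximum compressive stress" is the magnitude of
  the most negative principal value. Because the raw maximum sits at the
  reentrant craniectomy rim and can grow under refinement, the 99th and
  95th percentiles of the compressive principal stress are always reported
  alongside it.

## Study sizes and known limitations

The shipped studies run at deliberately modest sizes chosen as a
resolution/coverage compromise: property sweeps (opening radii 20–50 mm,
hemispheric injury cases, shear moduli 5–20 kPa) use ~3,200-element meshes
with 4 load steps; the solver-verification problems use ~18k–24k elements.
At sweep resolution the planning-curve quantities are converged to within a
few percent of the 20k-element values, which is ample for the ordering and
ratio properties they feed.

Known limitations, inherited from the model or chosen here:

* Homogeneous isotropic tissue; no falx/tentorium/dura, no ventricles, no
  gray/white contrast. Midline-shift magnitudes on the synthetic geometry
  are therefore smaller than subject-specific values (the membrane that
  transmits hemispheric pressure differences is absent).
* The skull is a rigid constraint with a sharp opening rim; peak stress at
  the rim is mesh-sensitive (hence the percentile reporting), and no
  contact mechanics acts at the edge.
* Stationary ICP only; the transient decay of ICP after opening is out of
  scope.
* On this geometry the maximum compressive stress does **not** scale
  proportionally with the shear modulus: the bulge grows as tissue softens,
  so strains are not μ-invariant, and the rim maximum carries a volumetric
  contribution $K(J_e-1)$ that is independent of μ altogether. The package
  reports the honest monotone behaviour (stress increases with μ;
  displacement and herniated volume decrease).

## Reproducing the numbers

```{r example}
library(dccsim)

geom <- build_idealized_head(
  c(80, 66, 59),
  list(opening_spec("unilateral_circular", radius_mm = 40)))
mesh <- mesh_head(geom, h = 16)

cfg <- scenario_config(
  openings = list(opening_spec("unilateral_circular", radius_mm = 40)),
  h_mm = 16, lambda_g = 1.1, solver = solver_options(n_load_steps = 5))
curve <- run_scenario(cfg, mesh)
curve
```

The command-line front end (`exec/dccsim`) drives the same stages from a
YAML file: `dccsim --config scenario.yaml scenario`.
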