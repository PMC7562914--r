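---
title: "The atherosim plaque-growth model: assumptions, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The atherosim plaque-growth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atherosim)
```

`atherosim` simulates early atherosclerotic plaque growth on idealized
coronary segments through three one-way-coupled levels: steady lumen
hemodynamics, endothelial and transmural transport with a ten-species
inflammation network, and strain-based wall thickening. This vignette is
the package's own account of the science: what is modelled, what is
assumed, which numbers are suspect, and which choices were genuinely open.

## 1. Geometry: what the synthetic generator emulates

Patient arteries enter this class of model as image-based 3-D
reconstructions. Those are replaced here by a parametric stand-in: a
straight axisymmetric tube of lumen radius $R_0$ (default 1.5 mm, a
typical proximal coronary calibre), wall thickness 0.75 mm (a modelling
choice — reconstruction papers rarely report it; config-exposed), and
optional Gaussian stenoses

$$ r(z) = R_0\Big(1 - \sum_k d_k\, e^{-(z - z_k)^2 / 2 w_k^2}\Big), $$

smooth and standard in idealized-stenosis CFD; no parametric lesion shape
is canonical, and a Gaussian exercises every downstream mechanism
(acceleration, separation, recovery). The default mesh edge length is
0.15 mm, matching the tetrahedral edge length such studies use; the demo
configuration uses 0.25 mm, which changes mid-tube shear by under 2 %
(grid-convergence test) while keeping a full 73-month run under a minute.

What the generator does *not* emulate: non-circular lumens, tapering,
curvature and side branches, eccentric lesions, intima/media layering, and
inter-patient geometric variability. Passing tests on these geometries
therefore validate the *mechanisms* (shear-gated influx, reaction
kinetics, growth bookkeeping), not patient-specific accuracy.

Only the axisymmetric-2D path is implemented; `dimensionality = "full-3D"`
errors. The physics of every level is fully exercisable axisymmetrically,
and 3-D tetrahedral meshing is tooling rather than method.

## 2. Hemodynamics

Blood is incompressible and Newtonian (ρ = 1060 kg/m³, μ = 0.0035 Pa·s),
the flow steady and laminar — over multi-year growth horizons the pulsatile
detail is irrelevant to the mean shear field, and lumen change is assumed
not to feed back into the flow (one-way coupling; the deformed geometry is
never re-solved within a run).

The solver uses the Stokes stream function ψ and azimuthal vorticity ω on
a body-fitted grid $(z, \eta = r/R(z))$:

$$ E^2\psi = -r\,\omega, \qquad
   u_z \partial_z \omega + u_r \partial_r \omega - \frac{u_r}{r}\omega
   = \nu\Big(\nabla^2\omega - \frac{\omega}{r^2}\Big), $$

iterated with under-relaxed Picard updates (adaptive relaxation, halved
when the update norm grows), first-order upwind advection of vorticity,
and a second-order one-sided wall-vorticity closure (the simpler two-point
closure is first-order for developed profiles and costs several percent of
wall shear). ESS is $\mu|\omega_\text{wall}|$.

Numerical contracts and their rationale:

* **Mass conservation is identical**: the volumetric flux through every
  cross-section equals $2\pi\psi_\text{wall}$ by construction, so the
  reported continuity residual (inlet/outlet flux imbalance) is at
  round-off, well inside the 1e-6 contract.
* **Pressure** is recovered as an axial profile from the viscous
  (Poiseuille) gradient plus a momentum-flux correction — the formulation
  eliminates the 2-D pressure field, and only the transmural difference
  Δp(z), which varies by a few Pa along a 30 mm segment, feeds the
  endothelium.
* Convergence tolerance 1e-6 on the relative vorticity change; a Reynolds
  number above 2000 triggers a laminar-assumption warning.
* Inlet profile parabolic by default (flat optional); the mean inlet
  velocity is a patient-level assumption — 0.15 m/s, a typical resting
  coronary mean, documented rather than fitted.

At the demo Reynolds number (~140) the solver reproduces the expected
stenosis physics: shear maximum slightly upstream of the throat and a
downstream separation region with near-zero shear — the "low-ESS"
sub-segments where the disease mechanism concentrates.

## 3. Endothelium: the shear/NO gate

Transport across the endothelium uses the Kedem–Katchalsky relations with
shear-regulated coefficients (hydraulic conductivity rising with shear,
diffusive permeability falling with shear via eNOS → NO). Three unit
issues in the published correlations had to be settled once:

* **Diffusive-permeability scale.** The correlation
  $DP = -6c_{NO} + 0.34$ yields order-0.3 numbers with no stated unit. The
  raw value is kept (all formula-level tests assert it) and multiplied by
  a single config knob, `permeability_unit_scale`. Its default is
  1e-9 m/s per formula unit: with that choice DP spans roughly
  (0.3–3.4)·10⁻¹⁰ m/s across the physiologic shear range — the measured
  order of endothelial LDL permeability — and the diffusive term dominates
  the convective leak $(1-\sigma_f)J_v\bar c$ at physiological transmural
  pressure, so the total lipoprotein influx *decreases* monotonically with
  shear. A scale of 1e-10 m/s would invert that: the convective term
  (which grows with shear through $L_p$) would dominate and high-shear
  faces would import *more* LDL, contradicting the low-shear-influx
  mechanism the permeability model exists to encode. This is the one
  place the package deviates from a natural first reading of the source
  constants, and it is deliberate.
* **pO₂ vs K_M units.** The NO saturation mixes an oxygen tension in mmHg
  (60) with a Michaelis constant in µM (4.7). Both are expressed in mmHg
  via the Henry-law solubility of O₂ in plasma (1.34 µM/mmHg, config), so
  K_M ≈ 3.51 mmHg and the ratio is dimensionless.
* **Monocyte coefficient m_r.** Tabulated as 5.5·10⁻⁴ m³/(mol·day); the
  day → second conversion is applied internally and the unit ambiguity
  (m³ vs m⁴ in different published statements of this coefficient) is
  carried as metadata, not resolved.

Stagnation faces: $\ln(\text{WSS})$ in the eNOS law is singular at zero
shear, so WSS is clamped to 1e-6 Pa *for that law only*; the hydraulic
conductivity law ($\ln(\text{WSS}+0.015)$) is finite at zero and is not
clamped.

## 4. Wall flow: the Darcy limit

Plasma filtration through the wall (porosity 0.96, Darcian permeability
1.2·10⁻¹⁸ m²) is solved as a steady pressure problem — the transient,
inertial and quadratic-loss terms of the full porous-momentum equations
are negligible at filtration velocities of order 10⁻⁸ m/s. The
finite-volume scheme uses exact radial two-point transmissibilities
($T = k\,2\pi\Delta z / \ln(r_2/r_1)$, the well-equation form), which makes
the discrete solution of pure radial filtration equal the analytic
cylindrical profile to round-off — the solver oracle asserts 1e-8 and
measures ~1e-15. The planar "slab" closed form $K\Delta p/\mu t$ is the
large-radius limit and is verified separately on a 500 mm-radius annulus.
Boundary conditions: prescribed Kedem–Katchalsky velocity (or pressure) at
the endothelium, pressure at the adventitia (17.5 mmHg, 30.5 mmHg for
hypertensive runs), sealed wall ends.

## 5. The inflammation network

Ten fields on the wall cells: LDL, HDL, OxLDL (mol/m³); monocytes,
macrophages, foam cells, contractile and synthetic SMCs (cells/m³);
cytokines (mol/m³); collagen (g/m³). Contractile SMCs start at
29.26·10¹² cells/m³, everything else at zero. Lipoproteins advect with the
filtration velocity and diffuse (8·10⁻¹³ m²/s); monocytes and macrophages
only diffuse (cells are too large to advect through the pores); foam
cells, SMCs and collagen are immobile. Cytokines are given the tabulated
diffusivity even though the printed cytokine balance omits transport — the
table row exists, and a signalling molecule that cannot move is the less
defensible reading.

Printed values kept verbatim, with their problems on the label:

* `m_d` = 2.572 s⁻¹ (monocyte apoptosis) is absurdly fast as printed —
  a monocyte would live under a second. It is stored as printed;
  `kinetic_parameters(preset = "literature_plausible")` reinterprets it
  per day.
* The SMC switching factor $(1 + e^{-S_r c_{cyt}/c_{c,max}})$ is
  dimensionless; as printed the phenotype equations have no rate constant.
  A `base_switch_rate_per_s` (default $S_r$ = 4.16·10⁻⁸ 1/s, the only
  printed rate in that law) supplies the units.
* The OxLDL production term is $+\gamma r_{LDL} c_{LDL}$ *without* the HDL
  protection factor, while the LDL sink includes it — an asymmetry kept
  exactly as printed and covered by a bookkeeping test
  (LDL lost = protection × OxLDL gained).
* `r_HDL` is not tabulated; it defaults to `r_LDL` (symmetric treatment).
* `K_lag` (0.1486) appears in no governing equation; stored unused.
* Two conflicting macrophage wall diffusivities circulate in published
  tabulations of these constants (8·10⁻¹⁵ and 8·10⁻¹³ m²/s); 8·10⁻¹⁵ is
  adopted (the value plainly attributed to macrophages in the wall), the
  conflict noted here.
* The adventitial "coefficient of LDL concentration" (0.005 normal /
  0.015 hypertensive) comes without a definition; it is read as the
  fraction of the lumen concentration imposed as a Dirichlet value at the
  adventitia, applied to both LDL and HDL. This is an interpretation, and
  it is isolated in `species_bc()`.

### Time integration

Each monthly macro-step is subdivided automatically (explicit-stability
limits for diffusion/advection, a 6-hour splitting cap) and advanced by
operator splitting: conservative explicit finite-volume transport, then
the reaction network by an *exact-linear* (exponential/φ₁) scheme — every
species whose kinetics are linear given its partners (decay + constant
source over the substep) is updated by the closed-form solution, and the
bilinear couplings (OxLDL–macrophage, cytokine production) freeze the
partner at its substep mean. Mass transfers (monocyte → macrophage →
foam cell; contractile → synthetic SMC) use the integrated closed forms,
so SMC switching conserves the total count *exactly* and frozen-input
trajectories match their analytic solutions to round-off. All updates
preserve nonnegativity by construction (exponential decays, upwind
advection, stability-limited diffusion).

Why this instead of a stiff implicit solve: the stiffest printed rate
(`m_d`) has a time constant of 0.4 s against a 2.6·10⁶ s macro-step; an
explicit reaction substep would need millions of steps and an implicit
Newton solve across 10 × n_cells unknowns is not warranted when the
network is linear-in-each-species. The scheme's accuracy is checked
against an adaptive 0-D integration (`deSolve::lsoda`, rtol 1e-8) of the
same network over six simulated years; the PDE path agrees to ~0.01 % per
species, two orders inside the 1 % contract.

### What the printed kinetics imply

At physiologic cytokine levels the switching factor is ≈ 2, so with the
default base rate nearly the whole contractile pool converts within
months, and the collagen equilibrium $g_r c_{sSMC}/d_g$ ≈ 1.6·10⁹ g/m³
pushes the plaque volume ratio far above 1. Two consequences, both
deliberate and documented rather than repaired:

* the volume ratio is capped (default 0.95, config-exposed) to keep the
  deformation geometrically valid, and multi-year runs saturate at that
  cap nearly uniformly;
* a patient with zero serum lipids still "grows" through this
  substrate-independent SMC/collagen background. The lipid-inflammation
  pathway itself (OxLDL, foam cells) is exactly zero in that case, which
  is what the pipeline test asserts.

The spatial *pattern* of the lipid pathway survives the saturation: OxLDL
accumulates preferentially in low-shear sub-segments (about twice the
throat level in the demo), and the wall-area gain of low-shear segments
exceeds the throat's — partly through the influx mechanism and partly
through geometry (equal inward displacement removes more area where the
lumen is wider).

## 6. Growth and wall thickening

$dV/V = c_{foam}V_{foam} + c_{sSMC}V_{sSMC} + c_{coll}v_{coll}$ per
element; the cellular volumes are **not** from the source model — they are
literature-order placeholders (5·10⁻¹⁵ m³ foam cell, 2.5·10⁻¹⁵ m³ SMC,
7.4·10⁻⁷ m³/g collagen, i.e. collagen density 1.35 g/cm³), config-exposed.
Thickening is constrained toward the centerline, so the directional strain
equals $dV/V$ exactly ($dl/l$ identity) and the default *kinematic* mode
displaces the endothelium inward by $\varepsilon\,l$ with the adventitia
and wall ends supported. The *elastic* mode solves, per axial station, the
radial linear-elastostatic annulus problem (E = 1.06 MPa, ν = 0.45) with
the growth strain as a radial eigenstrain, traction-free endothelium and
fixed adventitia — elasticity redistributes but does not set the
thickening, which is why kinematic is the default.

One geometric honesty note: $dl = \varepsilon l$ is the *slab* (cubic
element) identity. On a coronary-calibre annulus (R/t = 2) the achieved
element volume change is ~20 % below the prescribed ratio because inward
motion sweeps less volume at smaller radius; in the slab limit
(R/t ≫ 1) the audit closes to within a few percent, and that is the
geometry on which the growth-audit test asserts its 5 % agreement.

## 7. Morphometrics

Cross-sections every 0.5 mm (the CT slice thickness), aggregated six at a
time into 3 mm sub-segments with the trailing partial segment dropped —
the standard trick for suppressing registration error when comparing
simulated with imaged geometry. Plaque burden is
100·(vessel − lumen)/vessel with the vessel bounded by the adventitia (the
standard CT/IVUS definition; the term is used without definition in this
model class). Progression binarization uses a relative 20 % change with a
closed (≥) boundary, lumen decrease vs wall/burden increase; both the
relative reading and the boundary convention are config-exposed decisions.
Degenerate correlation (zero variance, e.g. identical geometries) is
reported as 1 by convention.

## 8. Problem sizes and determinism

Test and demo sizes were chosen as the smallest that exercise every
mechanism: the bundled demo runs a 30 mm artery at 0.25 mm resolution
(120 × 8 lumen, 120 × 3 wall cells) for 73 monthly macro-steps in well
under a minute; solver oracles use 0.15–0.5 mm grids. Everything is
deterministic — there is no Monte Carlo anywhere — so reruns with the same
configuration are bit-compatible up to floating-point associativity; seeds
are recorded as provenance, and results carry a configuration hash in
their manifest.

## 9. Known limitations

Axisymmetric geometry only; steady Newtonian flow (no pulsatility,
rheology, turbulence or fluid–structure interaction); single-layer wall
(no intima/media distinction, no leaky/normal junction decomposition, no
vesicular pathway); oxygen tension is a constant parameter, not a solved
field; no plaque-type classification beyond reporting the component
concentrations; the printed kinetic constants saturate multi-year runs as
described in §5; and cohort-level statistics (regression coefficients,
progression-prediction accuracies) are out of scope: they require serial
patient imaging datasets that are not distributable with a simulator.
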