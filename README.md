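# atherosim

Multi-level simulation of atherosclerotic plaque growth in idealized
coronary artery segments.

Atherosclerosis begins where the endothelium is mechanically stressed the
wrong way: regions of low endothelial shear stress (ESS) become more
permeable to low-density lipoprotein (LDL), which oxidizes inside the
arterial wall, recruits monocytes and macrophages, and ends as foam cells,
proliferating synthetic smooth muscle cells (SMCs) and collagen — the bulk
of an early plaque. `atherosim` is for computational-biomechanics
researchers who want a tested, desk-scale implementation of that whole
causal chain, from blood flow to wall thickening, on synthetic coronary
geometries.

## The model

Three one-way-coupled levels on an axisymmetric artery (lumen + porous
wall annulus):

1. **Hemodynamics.** Steady incompressible Newtonian flow
   (∇·U = 0, ρ U·∇U = −∇p + μ∇²U) solved in stream-function/vorticity
   form; the endothelial shear stress field is τ_w = μ|ω_wall|.
2. **Endothelium and wall transport.** Per-face Kedem–Katchalsky fluxes
   with shear- and nitric-oxide-regulated coefficients,

   - L_p = 0.2077·10⁻¹² ln(WSS + 0.015) + 3.1588·10⁻¹²
   - c_eNOS = 0.0033 ln(WSS) + 0.0322,  c_NO = 1.26 c_eNOS · pO₂/(pO₂ + K_M)
   - DP_LDL = DP_HDL = (−6 c_NO + 0.34)
   - J_v = L_p Δp,  J_s = DP Δc + (1 − σ_f) U c̄,
     J_mono = m_r/(1 + WSS/WSS₀) · c_OxLDL · c_mono

   feeding Darcy plasma filtration through the wall
   (U = −(K_perm/μ)∇p, porosity γ = 0.96) and a ten-species
   convection–diffusion–reaction network: HDL-protected LDL oxidation
   (factor −3·10⁻⁵c² + 5·10⁻⁴c + 1.0056), the
   monocyte → macrophage → foam-cell cascade, cytokine turnover,
   contractile → synthetic SMC switching, and collagen secretion, marched
   in monthly macro-steps.
3. **Wall thickening.** The end-state plaque volume ratio
   dV/V = c_foam V_foam + c_sSMC V_sSMC + c_coll v_coll becomes a
   centerline-directed strain ε = dV/V, displacing the endothelium inward
   by dl = ε·l (l the local wall thickness; an elastic eigenstrain mode is
   also provided).

Validation-style outputs mirror serial-imaging morphometrics: 0.5 mm
cross-sections, 3 mm sub-segments (six sections each), lumen area, wall
area, plaque burden and their changes, plus a 20 % progression
binarization.

## Worked example

A 30 mm segment (lumen radius 1.5 mm, wall 0.75 mm) with a 40 % Gaussian
stenosis at mid-length, cohort-mean boundary data (LDL 108.16 mg/dL,
HDL 55.96 mg/dL), simulated for two years at coarse (0.5 mm) resolution:

```r
library(atherosim)
cfg <- demo_config(edge_length_mm = 0.5, interscan_period_years = 2)
res <- run_plaque_growth(cfg)
res
#> <simulation_result>
#>   24 monthly steps, ESS 0.0283..11.2 Pa
#> # A tibble: 3 × 4
#>   metric        mean_change sd_change correlation
#>   <chr>               <dbl>     <dbl>       <dbl>
#> 1 lumen_area          -4.67     0.799       0.999
#> 2 wall_area            4.67     0.799       1
#> 3 plaque_burden       31.9      0.725       0.999
```

The shear field shows the expected physics — a maximum just upstream of
the throat and a separation region of very low shear downstream:

```r
ess <- res$ess
#> ESS: min 0.028 Pa at z = 19.8 mm, max 11.23 Pa at z = 14.2 mm
```

The per-segment table reads: mean lumen area shrank by 4.67 mm², the wall
gained the same area (the adventitia is supported), and plaque burden rose
by 31.9 percentage points — the printed kinetics saturate the SMC/collagen
pathway over multi-year horizons (see the methods vignette), so these
magnitudes characterize the published equation set, not a calibrated
patient. Oxidized LDL still localizes where it should: its wall
concentration in the low-shear sub-segments is about twice that at the
throat.

Useful entry points: `generate_synthetic_artery()`, `solve_lumen_flow()`,
`compute_ess()`, `endothelial_state()`, `solve_plasma_flow()`,
`step_species()` / `simulate_wellmixed()`, `apply_wall_thickening()`,
`segment_metrics()`, `compare_geometries()`, and `autoplot()` methods for
each result. A small CLI lives at `inst/cli/atherosim`
(`params --print-defaults`, `make-geometry`, `simulate`, `metrics`).

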