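#' Blood properties
#'
#' Density and dynamic viscosity of whole blood, treated as an incompressible
#' Newtonian fluid in the lumen.
#'
#' @param density_kg_m3 Blood density, kg/m^3.
#' @param viscosity_pa_s Dynamic viscosity, Pa s.
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(density_kg_m3 = 1060, viscosity_pa_s = 0.0035) {
  stopifnot(density_kg_m3 > 0, viscosity_pa_s > 0)
  structure(list(density_kg_m3 = density_kg_m3, viscosity_pa_s = viscosity_pa_s),
            class = "blood_properties")
}

#' Porous arterial-wall properties
#'
#' The wall is a rigid porous medium filtered by plasma in the Darcy limit.
#' The area porosity tensor is isotropic, `K = gamma * I`.
#'
#' @param plasma_density_kg_m3 Plasma density, kg/m^3.
#' @param plasma_viscosity_pa_s Plasma dynamic viscosity, Pa s.
#' @param porosity Volume porosity gamma, dimensionless in (0, 1].
#' @param darcian_permeability_m2 Darcian permeability, m^2.
#' @return An object of class `porous_wall_properties`.
#' @export
porous_wall_properties <- function(plasma_density_kg_m3 = 1000,
                                   plasma_viscosity_pa_s = 0.001,
                                   porosity = 0.96,
                                   darcian_permeability_m2 = 1.2e-18) {
  stopifnot(plasma_density_kg_m3 > 0, plasma_viscosity_pa_s > 0,
            darcian_permeability_m2 > 0)
  if (!(porosity > 0 && porosity <= 1)) {
    stop("porosity must lie in (0, 1], got ", porosity)
  }
  structure(list(plasma_density_kg_m3 = plasma_density_kg_m3,
                 plasma_viscosity_pa_s = plasma_viscosity_pa_s,
                 porosity = porosity,
                 darcian_permeability_m2 = darcian_permeability_m2),
            class = "porous_wall_properties")
}

#' Endothelial transport parameters
#'
#' Parameters of the shear- and nitric-oxide-regulated endothelial transport
#' sub-model: solvent reflection, the monocyte recruitment coefficient, the
#' reference shear stress, oxygen partial pressure, and the Michaelis
#' constant for NO production.
#'
#' The diffusive-permeability correlation returns a number of order 0.3 with
#' no stated unit; the raw value is kept and multiplied by
#' `permeability_unit_scale` (m/s per formula unit) to obtain a physical
#' permeability. The Michaelis constant is quoted in micromolar and the
#' oxygen tension in mmHg; `o2_solubility_um_per_mmhg` (Henry-law solubility
#' of O2 in plasma, default 1.34 uM/mmHg) converts the former to mmHg so the
#' saturation ratio is dimensionless.
#'
#' @param sigma_f Solvent reflection coefficient, in \[0, 1\].
#' @param m_r_m3_mol_day Monocyte flux coefficient, m^3/(mol day) as tabulated.
#' @param wss0_pa Reference wall shear stress, Pa.
#' @param po2_mmhg Oxygen partial pressure in the wall, mmHg.
#' @param k_m_um Michaelis constant for NO, micromolar.
#' @param permeability_unit_scale m/s per raw formula unit of the
#'   diffusive-permeability correlation.
#' @param o2_solubility_um_per_mmhg Henry-law O2 solubility used to express
#'   the Michaelis constant in mmHg.
#' @return An object of class `endothelial_parameters`.
#' @export
endothelial_parameters <- function(sigma_f = 0.997,
                                   m_r_m3_mol_day = 5.5e-4,
                                   wss0_pa = 1,
                                   po2_mmhg = 60,
                                   k_m_um = 4.7,
                                   permeability_unit_scale = 1e-9,
                                   o2_solubility_um_per_mmhg = 1.34) {
  stopifnot(sigma_f >= 0, sigma_f <= 1, wss0_pa > 0, po2_mmhg >= 0,
            k_m_um > 0, permeability_unit_scale > 0,
            o2_solubility_um_per_mmhg > 0)
  structure(list(sigma_f = sigma_f,
                 m_r_m3_mol_day = m_r_m3_mol_day,
                 wss0_pa = wss0_pa,
                 po2_mmhg = po2_mmhg,
                 k_m_um = k_m_um,
                 permeability_unit_scale = permeability_unit_scale,
                 o2_solubility_um_per_mmhg = o2_solubility_um_per_mmhg),
            class = "endothelial_parameters")
}

#' Kinetic parameters of the inflammation network
#'
#' All reaction-rate constants and wall diffusivities of the ten-species
#' network, with explicit unit annotations. Defaults are the tabulated
#' values; several are dimensionally suspicious as printed (notably the
#' monocyte apoptosis rate `m_d` = 2.572 1/s) and are kept verbatim, with a
#' `preset = "literature_plausible"` alternative that reinterprets those
#' rates per day.
#'
#' `base_switch_rate_per_s` supplies the 1/s scale missing from the printed
#' smooth-muscle-cell phenotype switching law, whose experimental factor
#' `(1 + exp(-S_r c_cyt / c_c_max))` is dimensionless; the default reuses
#' `S_r`. `r_HDL` is not tabulated; by default it mirrors `r_LDL`.
#' `K_lag` is tabulated but appears in no governing equation; it is stored
#' unused.
#'
#' @param preset `"printed"` (default) or `"literature_plausible"`.
#' @param ... Named overrides of individual entries.
#' @return An object of class `kinetic_parameters`: a named list of values
#'   with a `units` attribute.
#' @export
kinetic_parameters <- function(preset = c("printed", "literature_plausible"), ...) {
  preset <- match.arg(preset)
  p <- list(
    r_LDL = 1.4e-4,            # 1/s, LDL oxidation rate absent HDL
    r_HDL = 1.4e-4,            # 1/s, mirrored from r_LDL (not tabulated)
    k_1 = 0.0367e-4,           # m^3/(cells s), macrophage -> foam cell
    k_2 = 0.12e-17,            # m^3/(cells s), OxLDL uptake by macrophages
    m_d = 2.572,               # 1/s as printed, monocyte apoptosis
    d_m = 1.15e-6,             # 1/s, monocyte -> macrophage differentiation
    d_c = 2.3148e-5,           # 1/s, cytokine degradation
    d_r = 3.1e-10,             # m^3/(s cell), cytokine production
    S_r = 4.16e-8,             # 1/s, synthetic SMC production coefficient
    base_switch_rate_per_s = 4.16e-8,  # 1/s scale of the SMC switching law
    c_c_max = 4.2e9,           # mol/m^3, cytokine maximum concentration
    g_r = 2.157e-11,           # g/(cells s), collagen secretion
    d_g = 3.85e-7,             # 1/s, collagen degradation
    K_lag = 0.1486,            # dimensionless, tabulated but unused
    c_SMC_0 = 29.26e12,        # cells/m^3, contractile SMC intima concentration
    D_LDL_wall = 8e-13,        # m^2/s
    D_HDL_wall = 8e-13,        # m^2/s
    D_OxLDL_wall = 8e-13,      # m^2/s
    D_cytokine_wall = 8e-13,   # m^2/s
    D_monocyte = 1e-12,        # m^2/s
    D_macrophage_wall = 8e-15, # m^2/s
    adventitia_ldl_coef_normal = 0.005,
    adventitia_ldl_coef_hypertensive = 0.015,
    adventitia_pressure_normal_mmhg = 17.5,
    adventitia_pressure_hypertensive_mmhg = 30.5
  )
  if (preset == "literature_plausible") {
    # reinterpret the per-second-printed fast rates per day
    p$m_d <- 2.572 / 86400
    p$base_switch_rate_per_s <- p$S_r
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))))
  units <- c(
    r_LDL = "1/s", r_HDL = "1/s", k_1 = "m^3/(cells s)", k_2 = "m^3/(cells s)",
    m_d = "1/s (as printed)", d_m = "1/s", d_c = "1/s", d_r = "m^3/(s cell)",
    S_r = "1/s", base_switch_rate_per_s = "1/s", c_c_max = "mol/m^3",
    g_r = "g/(cells s)", d_g = "1/s", K_lag = "dimensionless (unused)",
    c_SMC_0 = "cells/m^3",
    D_LDL_wall = "m^2/s", D_HDL_wall = "m^2/s", D_OxLDL_wall = "m^2/s",
    D_cytokine_wall = "m^2/s", D_monocyte = "m^2/s",
    D_macrophage_wall = "m^2/s",
    adventitia_ldl_coef_normal = "dimensionless",
    adventitia_ldl_coef_hypertensive = "dimensionless",
    adventitia_pressure_normal_mmhg = "mmHg",
    adventitia_pressure_hypertensive_mmhg = "mmHg"
  )
  structure(p, units = units, preset = preset, class = "kinetic_parameters")
}

#' Cellular and specific volumes used for plaque volume
#'
#' Volume contributed per foam cell, per synthetic smooth muscle cell, and
#' per gram of collagen. These are NOT tabulated in the source model;
#' defaults are literature-order placeholders and should be reviewed for any
#' quantitative use.
#'
#' @param v_foam_m3 Foam cell volume, m^3/cell.
#' @param v_ssmc_m3 Synthetic SMC volume, m^3/cell.
#' @param v_collagen_m3_g Collagen specific volume, m^3/g.
#' @return An object of class `cellular_volumes`.
#' @export
cellular_volumes <- function(v_foam_m3 = 5e-15,
                             v_ssmc_m3 = 2.5e-15,
                             v_collagen_m3_g = 7.4e-7) {
  stopifnot(v_foam_m3 > 0, v_ssmc_m3 > 0, v_collagen_m3_g > 0)
  structure(list(v_foam_m3 = v_foam_m3, v_ssmc_m3 = v_ssmc_m3,
                 v_collagen_m3_g = v_collagen_m3_g),
            class = "cellular_volumes")
}

#' Linear-elastic wall material
#'
#' @param young_modulus_pa Young modulus, Pa.
#' @param poisson_ratio Poisson ratio, in (0, 0.5).
#' @return An object of class `wall_material`.
#' @export
wall_material <- function(young_modulus_pa = 1.06e6, poisson_ratio = 0.45) {
  stopifnot(young_modulus_pa > 0)
  if (!(poisson_ratio > 0 && poisson_ratio < 0.5)) {
    stop("poisson_ratio must lie in (0, 0.5), got ", poisson_ratio)
  }
  structure(list(young_modulus_pa = young_modulus_pa,
                 poisson_ratio = poisson_ratio),
            class = "wall_material")
}

#' All model parameters as a tidy table
#'
#' One row per parameter across the blood, wall, endothelium, kinetics,
#' growth and material blocks, with values and units. This is the
#' round-trippable record behind `atherosim params --print-defaults`.
#'
#' @param kinetics,endothelium,wall,blood,volumes,material Parameter objects;
#'   defaults are the printed model defaults.
#' @return A tibble with columns `block`, `parameter`, `value`, `unit`.
#' @export
parameter_table <- function(kinetics = kinetic_parameters(),
                            endothelium = endothelial_parameters(),
                            wall = porous_wall_properties(),
                            blood = blood_properties(),
                            volumes = cellular_volumes(),
                            material = wall_material()) {
  row <- function(block, parameter, value, unit) {
    tibble::tibble(block = block, parameter = parameter,
                   value = as.numeric(value), unit = unit)
  }
  ku <- attr(kinetics, "units")
  dplyr::bind_rows(
    row("blood", "density", blood$density_kg_m3, "kg/m^3"),
    row("blood", "viscosity", blood$viscosity_pa_s, "Pa s"),
    row("wall", "plasma_density", wall$plasma_density_kg_m3, "kg/m^3"),
    row("wall", "plasma_viscosity", wall$plasma_viscosity_pa_s, "Pa s"),
    row("wall", "porosity", wall$porosity, "dimensionless"),
    row("wall", "darcian_permeability", wall$darcian_permeability_m2, "m^2"),
    row("endothelium", "sigma_f", endothelium$sigma_f, "dimensionless"),
    row("endothelium", "m_r", endothelium$m_r_m3_mol_day, "m^3/(mol day)"),
    row("endothelium", "wss0", endothelium$wss0_pa, "Pa"),
    row("endothelium", "po2", endothelium$po2_mmhg, "mmHg"),
    row("endothelium", "k_m", endothelium$k_m_um, "uM"),
    row("endothelium", "permeability_unit_scale",
        endothelium$permeability_unit_scale, "m/s per formula unit"),
    purrr::map2_dfr(names(unclass(kinetics)), unclass(kinetics),
                    function(nm, v) row("kinetics", nm, v, unname(ku[nm]))),
    row("growth", "v_foam", volumes$v_foam_m3, "m^3/cell"),
    row("growth", "v_ssmc", volumes$v_ssmc_m3, "m^3/cell"),
    row("growth", "v_collagen", volumes$v_collagen_m3_g, "m^3/g"),
    row("material", "young_modulus", material$young_modulus_pa, "Pa"),
    row("material", "poisson_ratio", material$poisson_ratio, "dimensionless")
  )
}
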