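#' Endothelial hydraulic conductivity from wall shear stress
#'
#' `L_p = 0.2077e-12 * ln(WSS + 0.015) + 3.1588e-12`, with WSS in Pa.
#' Increasing in WSS; finite at WSS = 0 (ln 0.015).
#'
#' @param wss_pa Wall shear stress, Pa (>= 0).
#' @return Hydraulic conductivity (formula units, m/(Pa s) scale).
#' @export
hydraulic_conductivity <- function(wss_pa) {
  if (any(wss_pa < 0)) stop("WSS must be >= 0")
  0.2077e-12 * log(wss_pa + 0.015) + 3.1588e-12
}

#' Endothelial nitric-oxide synthase concentration from wall shear stress
#'
#' `c_eNOS = 0.0033 * ln(WSS) + 0.0322` (formula units, WSS in Pa).
#' Singular at WSS = 0: stagnation faces should be clamped by the caller
#' (see [endothelial_state()], which clamps below 1e-6 Pa).
#'
#' @param wss_pa Wall shear stress, Pa (> 0).
#' @return eNOS concentration (formula units).
#' @export
enos_concentration <- function(wss_pa) {
  if (any(wss_pa <= 0)) stop("WSS must be > 0 (log singularity at 0)")
  0.0033 * log(wss_pa) + 0.0322
}

#' Endothelial nitric-oxide concentration
#'
#' Michaelis-Menten saturation in the oxygen partial pressure:
#' `c_NO = 1.26 * c_eNOS * pO2 / (pO2 + K_M)`, with `K_M` expressed in the
#' same unit as `pO2` (mmHg; the micromolar Michaelis constant is converted
#' via the Henry-law O2 solubility).
#'
#' @param c_enos eNOS concentration (formula units).
#' @param po2_mmhg Oxygen partial pressure, mmHg (>= 0).
#' @param k_m_mmhg Michaelis constant in mmHg.
#' @return NO concentration (formula units).
#' @export
no_concentration <- function(c_enos, po2_mmhg, k_m_mmhg) {
  if (any(po2_mmhg < 0)) stop("pO2 must be >= 0")
  1.26 * c_enos * po2_mmhg / (po2_mmhg + k_m_mmhg)
}

#' Diffusive permeability of the endothelium to LDL and HDL
#'
#' `DP = (-6 c_NO + 0.34)`, floored at 0, in raw formula units; multiply by
#' `permeability_unit_scale` (see [endothelial_parameters()]) for m/s.
#' Decreasing in NO, hence decreasing in shear.
#'
#' @param c_no NO concentration (formula units).
#' @param unit_scale Scale factor to m/s; 1 returns raw formula units.
#' @return Diffusive permeability.
#' @export
diffusive_permeability <- function(c_no, unit_scale = 1) {
  pmax(-6 * c_no + 0.34, 0) * unit_scale
}

#' Kedem-Katchalsky volume flux
#'
#' `J_v = L_p * dp`; the osmotic term is neglected.
#'
#' @param l_p Hydraulic conductivity.
#' @param dp_pa Transmural pressure difference, Pa (lumen minus wall).
#' @return Volume flux (filtration velocity), same sign as `dp_pa`.
#' @export
volume_flux <- function(l_p, dp_pa) l_p * dp_pa

#' Kedem-Katchalsky solute flux
#'
#' `J_s = DP * dc + (1 - sigma_f) * U * c_mean`.
#'
#' @param dp Diffusive permeability, m/s.
#' @param dc Transmembrane concentration difference (lumen minus wall).
#' @param sigma_f Solvent reflection coefficient in \[0, 1\].
#' @param u Transmembrane volume flux (filtration velocity), m/s.
#' @param c_mean Mean membrane concentration.
#' @return Solute flux, concentration x velocity units.
#' @export
solute_flux <- function(dp, dc, sigma_f, u, c_mean) {
  if (any(sigma_f < 0 | sigma_f > 1)) stop("sigma_f must lie in [0, 1]")
  dp * dc + (1 - sigma_f) * u * c_mean
}

#' Shear-gated endothelial monocyte flux
#'
#' `J = m_r / (1 + WSS/WSS0) * c_OxLDL * c_monocytes,lumen`: recruitment is
#' proportional to the local oxidized-LDL signal and suppressed by high
#' shear.
#'
#' @param wss_pa Wall shear stress, Pa.
#' @param c_oxldl_wall OxLDL concentration at the wall side, mol/m^3.
#' @param c_mono_lumen Blood monocyte concentration, cells/m^3.
#' @param m_r Monocyte flux coefficient (per-second units).
#' @param wss0_pa Reference shear stress, Pa.
#' @return Monocyte flux, cells/(m^2 s) scale.
#' @export
monocyte_flux <- function(wss_pa, c_oxldl_wall, c_mono_lumen,
                          m_r = 5.5e-4 / 86400, wss0_pa = 1) {
  if (any(c_oxldl_wall < 0) || any(c_mono_lumen < 0)) {
    stop("concentrations must be >= 0")
  }
  m_r / (1 + wss_pa / wss0_pa) * c_oxldl_wall * c_mono_lumen
}

#' Per-face endothelial transport state
#'
#' Evaluates the full shear- and NO-regulated endothelial chain on each
#' endothelial face: hydraulic conductivity, eNOS, NO, diffusive
#' permeabilities, and the Kedem-Katchalsky volume and solute fluxes plus
#' the monocyte flux, given the lumen-side pressures and concentrations and
#' the current wall-side concentrations.
#'
#' Faces with WSS below 1e-6 Pa are clamped to 1e-6 Pa for the eNOS
#' correlation only (log singularity at stagnation).
#'
#' @param wss A `wall_shear_field` from [compute_ess()].
#' @param params An [endothelial_parameters()].
#' @param lumen_pressure_pa Lumen-side pressure per face (length 1 or nz), Pa.
#' @param wall_pressure_pa Wall-side (adventitial reference) pressure, Pa.
#' @param c_ldl_lumen,c_hdl_lumen Lumen concentrations, mol/m^3.
#' @param c_mono_lumen Blood monocyte concentration, cells/m^3.
#' @param c_ldl_wall,c_hdl_wall,c_oxldl_wall Wall-side concentrations at the
#'   endothelial face (length 1 or nz).
#' @return A tibble of class `endothelial_state`: one row per face with
#'   `wss_pa`, `l_p`, `c_enos`, `c_no`, `dp_m_s`, `j_v_m_s`, `j_s_ldl`,
#'   `j_s_hdl`, `j_monocytes`.
#' @export
endothelial_state <- function(wss, params = endothelial_parameters(),
                              lumen_pressure_pa, wall_pressure_pa,
                              c_ldl_lumen, c_hdl_lumen, c_mono_lumen,
                              c_ldl_wall = 0, c_hdl_wall = 0, c_oxldl_wall = 0) {
  stopifnot(inherits(wss, "wall_shear_field"))
  n <- nrow(wss)
  w <- wss$ess_pa
  lp <- hydraulic_conductivity(w)
  enos <- enos_concentration(pmax(w, 1e-6))
  k_m_mmhg <- params$k_m_um / params$o2_solubility_um_per_mmhg
  cno <- no_concentration(enos, params$po2_mmhg, k_m_mmhg)
  dp_perm <- diffusive_permeability(cno, params$permeability_unit_scale)
  dpres <- rep(lumen_pressure_pa, length.out = n) - wall_pressure_pa
  jv <- volume_flux(lp, dpres)
  cl_w <- rep(c_ldl_wall, length.out = n)
  ch_w <- rep(c_hdl_wall, length.out = n)
  cox_w <- rep(c_oxldl_wall, length.out = n)
  js_ldl <- solute_flux(dp_perm, c_ldl_lumen - cl_w, params$sigma_f, jv,
                        (c_ldl_lumen + cl_w) / 2)
  js_hdl <- solute_flux(dp_perm, c_hdl_lumen - ch_w, params$sigma_f, jv,
                        (c_hdl_lumen + ch_w) / 2)
  m_r_s <- params$m_r_m3_mol_day / 86400
  jm <- monocyte_flux(w, cox_w, c_mono_lumen, m_r_s, params$wss0_pa)
  out <- tibble::tibble(
    face_id = wss$face_id, z_mm = wss$z_mm, wss_pa = w,
    l_p = lp, c_enos = enos, c_no = cno, dp_m_s = dp_perm,
    dp_pa = dpres, j_v_m_s = jv,
    j_s_ldl = js_ldl, j_s_hdl = js_hdl, j_monocytes = jm
  )
  class(out) <- c("endothelial_state", class(out))
  out
}
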