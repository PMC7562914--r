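#' Unit conversion helpers
#'
#' Geometry is held in millimetres, clinical pressures in mmHg and lipid
#' panels in mg/dL; the solvers work in SI. These helpers concentrate every
#' conversion in one place.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * 133.322387415

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / 133.322387415

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
months_to_seconds <- function(x) x * 2629800  # mean Gregorian month (365.25/12 d)

#' @rdname units
#' @export
years_to_seconds <- function(x) x * 31557600  # Julian year, 365.25 d

#' @rdname units
#' @export
days_to_seconds <- function(x) x * 86400

#' Convert a serum lipoprotein concentration from mg/dL to mol/m^3
#'
#' Clinical lipid panels report mass concentration; the transport model works
#' in molar units. The conversion uses an effective molar mass per particle
#' class (a documented convention, configurable): LDL 386.65 kg/mol and HDL
#' 175 kg/mol by default.
#'
#' @param mg_dl Concentration in mg/dL.
#' @param molar_mass_kg_mol Effective molar mass in kg/mol.
#' @return Concentration in mol/m^3.
#' @export
mg_dl_to_mol_m3 <- function(mg_dl, molar_mass_kg_mol) {
  stopifnot(molar_mass_kg_mol > 0)
  # mg/dL -> kg/m^3 is * 0.01; then / (kg/mol) -> mol/m^3
  mg_dl * 0.01 / molar_mass_kg_mol
}
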