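#' Physical constants and unit conversions
#'
#' Internal unit system: lengths in nm, energies in kJ/mol, times in ps,
#' forces in kJ/mol/nm. Conversions to reporting units (mN/m for area
#' compressibility, cm^2/s for diffusivity, cm/s for permeability) happen
#' only at the reporting boundary, through the helpers below.
#'
#' @name units
#' @keywords internal
NULL

# Boltzmann constant, kJ/mol/K (equals the molar gas constant R in kJ/mol/K)
.kB_kJmol <- 0.0083144621

# Boltzmann constant, J/K
.kB_J <- 1.380649e-23

#' Thermal energy kB*T in kJ/mol
#' @param temperature temperature in K
#' @return numeric, kJ/mol
#' @export
kBT_kJmol <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB_kJmol * temperature
}

# 1 nm^2/ps = 1e-14 cm^2 / 1e-12 s = 1e-2 cm^2/s
.nm2ps_to_cm2s <- 1e-2

# 1 ps/nm = 1e-12 s / 1e-7 cm = 1e-5 s/cm  (resistance to permeation)
.psnm_to_scm <- 1e-5

# 1 nm/ps = 1e-7 cm / 1e-12 s = 1e5 cm/s  (permeability)
.nmps_to_cms <- 1e5

#' Convert a diffusivity from nm^2/ps to cm^2/s
#' @param d diffusivity in nm^2/ps
#' @return diffusivity in cm^2/s
#' @export
diffusivity_to_cm2s <- function(d) d * .nm2ps_to_cm2s

#' Convert a permeation resistance from ps/nm to s/cm
#' @param r resistance in ps/nm
#' @return resistance in s/cm
#' @export
resistance_to_scm <- function(r) r * .psnm_to_scm

#' Convert an area compressibility modulus from kJ/mol/nm^2 to mN/m
#'
#' kBT-per-area fluctuation estimators are naturally computed per molecule
#' (Avogadro-free) so the conversion uses the per-particle Boltzmann constant:
#' 1 kJ/mol/nm^2 = 1000/6.02214076e23 J / 1e-18 m^2 = 1.66054e-3 N/m.
#' @param ka modulus in kJ/mol/nm^2
#' @return modulus in mN/m
#' @export
ka_to_mNm <- function(ka) ka * (1000 / 6.02214076e23) / 1e-18 * 1e3
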