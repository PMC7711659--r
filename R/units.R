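# Physical constants (SI, CODATA 2018) and the unit conventions used
# throughout the package:
#   length          nm
#   energy          kT (thermal units at the system temperature)
#   charge          e  (elementary charges)
#   concentration   mol/L for user-facing values; number density nm^-3 inside
#   diffusion       m^2/s user-facing; nm^2/ns inside (1 m^2/s = 1e9 nm^2/ns)
#   voltage         mV user-facing; dimensionless z*eU/kT inside
#   current         pA

.kB <- 1.380649e-23      # J/K
.e_charge <- 1.602176634e-19  # C
.eps0 <- 8.8541878128e-12     # F/m
.N_A <- 6.02214076e23

#' Particles per nm^3 in a 1 mol/L solution
#'
#' The fixed conversion constant between molar concentration and number
#' density: 1 mol/L = 0.602214076 particles/nm^3.
#' @return A number (particles nm^-3 per mol/L).
#' @export
molar_to_density <- function() 0.602214076

#' Bjerrum length of a uniform dielectric
#'
#' Distance at which two unit charges in a medium of relative permittivity
#' `dielectric` interact with exactly 1 kT: lB = e^2 / (4 pi eps0 eps kT).
#'
#' @param dielectric Relative permittivity (dimensionless, > 1).
#' @param temperature Absolute temperature in K.
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length(78.45, 298.15)  # about 0.714 nm in water at 25 C
#' @export
bjerrum_length <- function(dielectric, temperature = 298.15) {
  stopifnot(dielectric > 1, temperature > 0)
  1e9 * .e_charge^2 / (4 * pi * .eps0 * dielectric * .kB * temperature)
}

#' Thermal voltage kT/e
#'
#' @param temperature Absolute temperature in K.
#' @return kT/e in mV (about 25.69 mV at 298.15 K).
#' @export
thermal_voltage_mV <- function(temperature = 298.15) {
  1000 * .kB * temperature / .e_charge
}

# elementary charge expressed in pA * ns (current unit bookkeeping)
.e_pA_ns <- .e_charge * 1e21
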