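# Canonical internal units: length in Angstrom, time in ns, energy in kcal/mol.
# Permeability is reported in cm/s (1 A/ns = 10 cm/s); concentration in
# molecules/A^3 with 1 M = 6.022140857e-4 molecules/A^3.  All conversions go
# through these constants so unit drift cannot creep in.

#' Physical constants and unit conversions
#'
#' Boltzmann constant in kcal/mol/K, unit-conversion factors between the
#' package's canonical units (Angstrom, ns, kcal/mol) and reporting units
#' (cm/s, molar), and the molarity of pure water used when converting water
#' counts into aqueous volumes.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 1.987204e-3 kcal/mol/K.}
#'   \item{A_per_ns_to_cm_s}{10: multiply a permeability in Angstrom/ns by this
#'     to obtain cm/s.}
#'   \item{molar_to_per_A3}{6.022140857e-4: molecules per cubic Angstrom in a
#'     1 M solution.}
#'   \item{water_molarity}{55.345 M, molarity of pure water; one water
#'     molecule accounts for 1/(55.345 * molar_to_per_A3) cubic Angstrom of
#'     aqueous volume.}
#'   \item{avogadro}{Avogadro's number.}
#' }
#' @export
bmc_constants <- list(
  kB              = 1.987204e-3,
  A_per_ns_to_cm_s = 10,
  molar_to_per_A3 = 6.022140857e-4,
  water_molarity  = 55.345,
  avogadro        = 6.02214076e23
)

#' Thermodynamic constants at a given temperature
#'
#' Bundles the temperature, Boltzmann constant and inverse temperature
#' beta = 1/(kB*T) used throughout the free-energy and permeability
#' calculations.
#'
#' @param T_K Temperature in Kelvin (default 298, the simulated temperature).
#' @return An object of class `ThermoConstants`: list with `T`, `kB`
#'   (kcal/mol/K), `kBT` (kcal/mol) and `beta` (mol/kcal).
#' @examples
#' th <- thermo_constants(298)
#' th$kBT  # 0.5924... kcal/mol
#' @export
thermo_constants <- function(T_K = 298) {
  stopifnot(is.numeric(T_K), length(T_K) == 1, T_K > 0)
  kB <- bmc_constants$kB
  structure(
    list(T = T_K, kB = kB, kBT = kB * T_K, beta = 1 / (kB * T_K)),
    class = "ThermoConstants"
  )
}

# internal: coerce a user-supplied thermo argument
as_thermo <- function(thermo) {
  if (inherits(thermo, "ThermoConstants")) return(thermo)
  if (is.numeric(thermo) && length(thermo) == 1) return(thermo_constants(thermo))
  stop("`thermo` must be a ThermoConstants object or a temperature in K")
}
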