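#' @useDynLib microrheo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft optim integrate rnorm approx coef lm mvfft sd var
#' @importFrom utils head tail read.table write.table
NULL

## Physical constants (CODATA 2018) in the package's "real" unit system:
## length A, energy kcal/mol, mass g/mol, temperature K, time ns.
.const <- list(
  kB        = 1.987204259e-3,   # kcal/(mol K); R / 4184
  avogadro  = 6.02214076e23,    # 1/mol
  e2_coul   = 332.06371,        # e^2/(4 pi eps0) in kcal A / mol
  # 1 g/mol expressed in the energy-consistent mass unit kcal ns^2/(mol A^2):
  # KE[J/mol] = 1e-3 kg * (0.1 m/s)^2 * m[g/mol] v[A/ns]^2 -> 1e-5/4184 kcal
  mass_si   = 1e-5 / 4184,
  # 1 atm in kcal/(mol A^3): 101325 Pa / (4184/NA * 1e30) Pa
  atm       = 101325 / (4184 / 6.02214076e23 * 1e30),
  # 1 kcal/(mol A^3) in Pa
  modulus_pa = 4184 / 6.02214076e23 * 1e30
)

#' Unit system for condensate microrheology
#'
#' The package works throughout in "real" molecular-dynamics units: length in
#' Angstrom, energy in kcal/mol, mass in g/mol, temperature in K, and time in
#' ns. Frequencies are 1/ns and moduli kcal/(mol A^3). Because this unit set is
#' not internally consistent, masses are converted to the energy-consistent
#' unit kcal ns^2/(mol A^2) wherever they enter equations of motion (see
#' [mass_internal()]).
#'
#' @return A list with fields `length`, `energy`, `mass`, `temperature`,
#'   `time`, the Boltzmann constant `kB` (kcal/(mol K)), the intrinsic MD time
#'   unit `intrinsic_time_fs` (the time unit implied by 1 A, 1 kcal/mol and
#'   1 g/mol, in femtoseconds), and conversion constants `atm_to_modulus`
#'   (atm to kcal/(mol A^3)) and `modulus_to_Pa`.
#' @examples
#' u <- unit_system()
#' u$kB
#' u$intrinsic_time_fs  # about 48.89 fs
#' @export
unit_system <- function() {
  list(
    length = "angstrom",
    energy = "kcal/mol",
    mass = "g/mol",
    temperature = "K",
    time = "ns",
    kB = .const$kB,
    # 1 A * sqrt(1 g/mol / (1 kcal/mol)) in fs:
    # 1e-10 m * sqrt(1e-3 / 4184) s = 4.8888e-14 s
    intrinsic_time_fs = 1e-10 * sqrt(1e-3 / 4184) * 1e15,
    atm_to_modulus = .const$atm,
    modulus_to_Pa = .const$modulus_pa
  )
}

#' Convert a mass in g/mol to energy-consistent internal units
#'
#' Returns the mass in kcal ns^2/(mol A^2), the unit in which kinetic energy is
#' `m v^2 / 2` with velocities in A/ns. Needed whenever mass enters a formula
#' together with energies in kcal/mol (equipartition, inertial terms of the
#' generalized Stokes-Einstein relation, Langevin dynamics).
#'
#' @param m_gmol mass in g/mol.
#' @return mass in kcal ns^2/(mol A^2).
#' @examples
#' # thermal velocity of a 100 g/mol bead at 300 K, in A/ns:
#' sqrt(unit_system()$kB * 300 / mass_internal(100))
#' @export
mass_internal <- function(m_gmol) m_gmol * .const$mass_si

#' Convert a friction coefficient between unit conventions
#'
#' Friction spectra are carried in kcal ns/(mol A^2) (so that
#' `Z = kB T / D` holds with D in A^2/ns). This converts to/from the
#' mass-based convention g/(mol ns).
#'
#' @param z friction value(s).
#' @param to `"g_mol_ns"` or `"kcal_ns"`.
#' @return converted friction.
#' @export
friction_convert <- function(z, to = c("g_mol_ns", "kcal_ns")) {
  to <- match.arg(to)
  if (to == "g_mol_ns") z / .const$mass_si else z * .const$mass_si
}
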