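# Physical constants (CODATA 2018) and unit conversions.
# Internal conventions: energies kJ/mol, lengths angstrom, angles radians,
# masses amu.  Electron-volts are accepted at I/O boundaries.

#' Unit conversion and physical constants
#'
#' A named list of the constants used throughout the package:
#' \describe{
#'   \item{ev_to_kjmol}{1 eV in kJ/mol (96.485).}
#'   \item{coulomb_ev_ang}{Coulomb prefactor e^2/(4 pi eps0) in eV angstrom.}
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{amu_kg}{Atomic mass unit in kg.}
#'   \item{c_cm_s}{Speed of light in cm/s.}
#' }
#' @export
unit_constants <- list(
  ev_to_kjmol   = 96.485,
  coulomb_ev_ang = 14.399645,
  avogadro      = 6.02214076e23,
  amu_kg        = 1.66053906660e-27,
  c_cm_s        = 2.99792458e10
)

#' Convert degrees to radians
#' @param x angle(s) in degrees
#' @return angle(s) in radians
#' @export
deg2rad <- function(x) x * pi / 180

#' Convert radians to degrees
#' @param x angle(s) in radians
#' @return angle(s) in degrees
#' @export
rad2deg <- function(x) x * 180 / pi

#' Convert energies between eV and kJ/mol
#'
#' @param x energies
#' @param from,to one of `"eV"` or `"kJmol"`
#' @return converted energies
#' @export
convert_energy <- function(x, from = c("eV", "kJmol"), to = c("kJmol", "eV")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) return(x)
  if (from == "eV") x * unit_constants$ev_to_kjmol else x / unit_constants$ev_to_kjmol
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(phi) {
  w <- phi - 2 * pi * floor((phi + pi) / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# Eigenvalue of the mass-weighted Hessian (kJ/mol / (amu ang^2)) -> wavenumber
# (cm^-1).  Negative eigenvalues are reported as negative wavenumbers.
mwh_eigenvalue_to_wavenumber <- function(lambda) {
  uc <- unit_constants
  si <- lambda * 1e3 / (uc$avogadro * uc$amu_kg * 1e-20)  # 1/s^2
  sign(si) * sqrt(abs(si)) / (2 * pi * uc$c_cm_s)
}

# standard atomic masses (amu); D is the deuterium isotope, H/D isotopic
atomic_masses <- c(
  H = 1.007825032, D = 2.014101778, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998403163, P = 30.973761998, S = 32.06, Cl = 35.45,
  I = 126.90447
)

lookup_masses <- function(symbols) {
  m <- atomic_masses[symbols]
  if (anyNA(m)) {
    stop("no tabulated mass for element(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
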