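# Physical constants and unit conversions.
#
# Internal mechanical unit system: amu / Angstrom / fs (so energies are in
# amu A^2 fs^-2). Spectroscopic frequencies are wavenumbers (cm^-1), Gibbs
# energies kcal/mol, dipoles Debye, densities nm^-3.

#' Physical constants used throughout the package
#'
#' A named list of CODATA-2018 constants expressed in the package's internal
#' unit system (amu, Angstrom, fs; wavenumbers in cm^-1; energies in
#' kcal/mol where molar).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{c_cm_s}{speed of light, cm/s}
#'   \item{c_cm_fs}{speed of light, cm/fs}
#'   \item{kB_kcal_mol}{Boltzmann (gas) constant, kcal mol^-1 K^-1}
#'   \item{kB_amu_A2_fs2}{Boltzmann constant, amu A^2 fs^-2 K^-1}
#'   \item{c2_cm_K}{second radiation constant h c / k_B, cm K}
#'   \item{au_density_nm3}{electron density unit conversion, 1 a.u. (e/bohr^3)
#'     in nm^-3}
#'   \item{bohr_A}{Bohr radius in Angstrom}
#' }
#' @export
phys_const <- list(
  c_cm_s        = 2.99792458e10,
  c_cm_fs       = 2.99792458e-5,
  kB_kcal_mol   = 1.987204259e-3,
  kB_amu_A2_fs2 = 8.31446262e-7,
  c2_cm_K       = 1.438776877,
  au_density_nm3 = 6748.33,
  bohr_A        = 0.529177210903
)

# covalent radii (Angstrom): Cordero consensus values for the heavy
# atoms; the classic 0.37 for H (the smaller modern H radius misses the
# H-H bond of H2 at the 1.15 perception scale)
.covalent_radii <- c(
  H = 0.37, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Fe = 1.32, Cu = 1.32, Zn = 1.22,
  Br = 1.20, I = 1.39, Se = 1.20
)

.atomic_masses <- c(
  H = 1.00794, He = 4.002602, Li = 6.941, Be = 9.012182, B = 10.811,
  C = 12.0107, N = 14.0067, O = 15.9994, F = 18.9984032, Ne = 20.1797,
  Na = 22.98977, Mg = 24.305, Al = 26.981538, Si = 28.0855, P = 30.973761,
  S = 32.065, Cl = 35.453, Ar = 39.948, K = 39.0983, Ca = 40.078,
  Fe = 55.845, Cu = 63.546, Zn = 65.38, Br = 79.904, I = 126.90447,
  Se = 78.96
)

.known_elements <- names(.covalent_radii)

#' Covalent radius of an element
#' @param element character vector of element symbols
#' @return numeric vector of covalent radii in Angstrom
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Standard atomic mass of an element
#' @param element character vector of element symbols
#' @return numeric vector of masses in amu
#' @export
atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
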