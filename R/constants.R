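## Physical constants used package-wide. Units: energy kJ/mol, length nm,
## charge e, dipole e.nm. Fields in kJ/(mol e nm), potentials in kJ/(mol e).

#' Physical constants
#'
#' Constants used throughout the package, in the package unit system
#' (energy kJ/mol, length nm, charge e).
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, 8.314462618e-3 kJ/(mol K).}
#'   \item{coulomb}{Coulomb prefactor 1/(4 pi eps0) = 138.935458
#'     kJ mol^-1 nm e^-2.}
#'   \item{voltPerNm}{Conversion of a field in V/nm acting on a unit charge
#'     to kJ/(mol e nm): 96.4853.}
#'   \item{eNmToDebye}{1 e nm = 48.0321 Debye.}
#' }
#' @export
PMM_CONSTANTS <- list(
  kB         = 8.314462618e-3,
  coulomb    = 138.935458,
  voltPerNm  = 96.4853,
  eNmToDebye = 48.0321
)

## Isotope-averaged atomic masses (u) for center-of-mass computation.
.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, Se = 78.971
)

#' Atomic mass lookup
#'
#' @param element Character vector of element symbols.
#' @return Numeric masses in unified atomic mass units.
#' @keywords internal
atomicMass <- function(element) {
  m <- .ATOMIC_MASSES[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Numerically stable log of the mean of exponentials
#'
#' Computes log(mean(exp(x))) in shifted form so that arguments with
#' magnitudes of order beta * |dU| (easily several hundred for realistic
#' perturbation energies) do not overflow.
#'
#' @param x Numeric vector.
#' @return log(mean(exp(x))) as a scalar.
#' @keywords internal
logMeanExp <- function(x) {
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  m <- max(x)
  m + log(mean(exp(x - m)))
}
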