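# Unit conventions used throughout the package:
#   energies eV, vibrational frequencies cm^-1, time fs,
#   dimensionless mass-frequency-scaled normal coordinates (GS minimum at q = 0).
# All conversions are centralized here.

#' Physical constants
#'
#' `HBAR_EV_FS` is the reduced Planck constant in eV·fs; `CM1_TO_EV` converts
#' a wavenumber in cm^-1 to an energy in eV.
#'
#' @format Numeric scalars.
#' @name constants
#' @aliases HBAR_EV_FS CM1_TO_EV
#' @export
HBAR_EV_FS <- 0.6582119569

#' @rdname constants
#' @export
CM1_TO_EV <- 1.239841984e-4

#' Unit conversions
#'
#' Convert between wavenumbers (cm^-1) and energies (eV), obtain the classical
#' vibrational period of a mode, and convert a Gaussian FWHM to its standard
#' deviation.
#'
#' @param nu_cm1 frequency in cm^-1.
#' @param e_ev energy in eV.
#' @param fwhm full width at half maximum (any unit; the result shares it).
#' @return A numeric vector in the target unit.
#' @examples
#' vib_period_fs(1600) # ~20.85 fs
#' @export
cm1_to_ev <- function(nu_cm1) nu_cm1 * CM1_TO_EV

#' @rdname cm1_to_ev
#' @export
ev_to_cm1 <- function(e_ev) e_ev / CM1_TO_EV

#' @rdname cm1_to_ev
#' @export
vib_period_fs <- function(nu_cm1) 2 * pi * HBAR_EV_FS / cm1_to_ev(nu_cm1)

#' @rdname cm1_to_ev
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
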