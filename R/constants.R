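# Physical constants in the package's internal units:
# energies in ueV, lengths in Angstrom, times in ps, temperatures in K.

# hbar in ueV * ps (6.582119569e-16 eV s)
HBAR_UEV_PS <- 658.2119569

# Quasi-harmonic conversion constant: <k> [N/m] = QH_CONST / (d<u2>/dT [A^2/K]).
# This is 2 k_B expressed so that <k> comes out in Newton per meter when the
# mean square displacement is in Angstrom squared and T in Kelvin.
QH_CONST <- 0.002761

# Reference temperature, 37 degrees C
T_REF_K <- 310.15

#' Gaussian-approximation convention constant
#'
#' The elastic incoherent intensity is modelled package-wide as
#' \eqn{S_{el}(Q,T) \propto \exp(-\langle u^2 \rangle Q^2 / c)} with
#' \eqn{c = 6} by default, consistent with
#' \eqn{\langle u^2 \rangle = 2 R_g^2} for the full (3-dimensional)
#' mean square displacement. The constant is shared by the synthetic
#' generator and the elastic fitter, so the two can never disagree; it can
#' be overridden through \code{options(ribodyn.gauss_constant = )}, which
#' rescales extracted MSDs (and hence force constants inversely) but leaves
#' generator/fitter round trips exact.
#'
#' @return The convention constant currently in force (numeric scalar).
#' @export
gauss_constant <- function() {
  c0 <- getOption("ribodyn.gauss_constant", 6)
  stopifnot(is.numeric(c0), length(c0) == 1L, c0 > 0)
  c0
}

#' Convert a Gaussian full width at half maximum to a standard deviation
#'
#' @param fwhm Full width at half maximum (any unit).
#' @return Standard deviation in the same unit
#'   (\code{fwhm / (2 sqrt(2 ln 2))}).
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
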