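#' Instrument configuration
#'
#' Describes a neutron spectrometer setting: incident wavelength, energy
#' resolution, accessible momentum-transfer range and, for quasi-elastic
#' settings, the energy-transfer grid.
#'
#' @param name Label for the configuration.
#' @param wavelength Incident wavelength in Angstrom.
#' @param resolution_fwhm Instrumental energy resolution (FWHM) in ueV.
#' @param q_min,q_max Momentum-transfer range in inverse Angstrom.
#' @param n_q Number of Q points (detector groups).
#' @param energy_window Half-width of the energy-transfer grid in ueV
#'   (QENS settings only; \code{NULL} for elastic fixed-window scans).
#' @param n_energy Number of energy-transfer points (QENS only).
#'
#' @return An object of class \code{instrument_config}.
#' @export
instrument_config <- function(name, wavelength, resolution_fwhm,
                              q_min, q_max, n_q,
                              energy_window = NULL, n_energy = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(wavelength > 0, resolution_fwhm > 0)
  stopifnot(q_min > 0, q_min < q_max, n_q >= 2)
  if (!is.null(energy_window)) {
    stopifnot(energy_window > 0, !is.null(n_energy), n_energy >= 16)
  }
  structure(list(name = name, wavelength = wavelength,
                 resolution_fwhm = resolution_fwhm,
                 q_min = q_min, q_max = q_max, n_q = as.integer(n_q),
                 energy_window = energy_window,
                 n_energy = if (is.null(n_energy)) NULL else as.integer(n_energy)),
            class = "instrument_config")
}

#' Instrument presets
#'
#' Built-in configurations for the two spectrometer types used throughout:
#' \describe{
#'   \item{\code{IN16}}{backscattering elastic fixed-window setting:
#'     6.27 Angstrom, 0.9 ueV FWHM (~1 ns window), Q 0.19--1.89 1/A,
#'     20 detector groups.}
#'   \item{\code{IN5_5.1A}}{time-of-flight QENS at 5.1 Angstrom, 75 ueV
#'     FWHM, Q 0.21--1.98 1/A.}
#'   \item{\code{IN5_10A}}{time-of-flight QENS at 10 Angstrom, 12 ueV
#'     FWHM, Q 0.10--1.01 1/A.}
#' }
#'
#' @param preset One of \code{"IN16"}, \code{"IN5_5.1A"}, \code{"IN5_10A"}.
#' @return An \code{instrument_config}.
#' @export
instrument_preset <- function(preset = c("IN16", "IN5_5.1A", "IN5_10A")) {
  preset <- match.arg(preset)
  switch(preset,
    "IN16" = instrument_config("IN16", wavelength = 6.27,
                               resolution_fwhm = 0.9,
                               q_min = 0.19, q_max = 1.89, n_q = 20L),
    "IN5_5.1A" = instrument_config("IN5_5.1A", wavelength = 5.1,
                                   resolution_fwhm = 75,
                                   q_min = 0.21, q_max = 1.98, n_q = 20L,
                                   energy_window = 1000, n_energy = 401L),
    "IN5_10A" = instrument_config("IN5_10A", wavelength = 10,
                                  resolution_fwhm = 12,
                                  q_min = 0.10, q_max = 1.01, n_q = 16L,
                                  energy_window = 400, n_energy = 801L))
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf("<instrument_config> %s: lambda %.2f A, resolution %.3g ueV FWHM\n",
              x$name, x$wavelength, x$resolution_fwhm))
  cat(sprintf("  Q %.3g - %.3g 1/A (%d points)\n", x$q_min, x$q_max, x$n_q))
  if (!is.null(x$energy_window))
    cat(sprintf("  energy window +/- %.3g ueV (%d points)\n",
                x$energy_window, x$n_energy))
  invisible(x)
}

#' Momentum-transfer and energy grids of an instrument setting
#'
#' @param instrument An \code{instrument_config}.
#' @return \code{q_grid}: evenly spaced Q values (1/A);
#'   \code{omega_grid}: symmetric energy-transfer grid (ueV).
#' @export
q_grid <- function(instrument) {
  stopifnot(inherits(instrument, "instrument_config"))
  seq(instrument$q_min, instrument$q_max, length.out = instrument$n_q)
}

#' @rdname q_grid
#' @export
omega_grid <- function(instrument) {
  stopifnot(inherits(instrument, "instrument_config"))
  if (is.null(instrument$energy_window))
    stop("instrument '", instrument$name, "' has no energy grid (elastic setting)")
  seq(-instrument$energy_window, instrument$energy_window,
      length.out = instrument$n_energy)
}

resolution_sigma <- function(instrument) fwhm_to_sigma(instrument$resolution_fwhm)
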