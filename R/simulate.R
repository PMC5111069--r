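# Synthetic-data generator emulating the backscattering elastic-window and
# time-of-flight QENS measurements, with known ground truth so every
# downstream stage is testable by parameter recovery.

#' Counting-noise specification
#'
#' @param mode \code{"none"} for noiseless expectation values (sigma 0) or
#'   \code{"poisson"} for Poisson counting statistics.
#' @param counts_scale Expected counts for a unit-shape bin (the elastic
#'   peak of an undamped sample at the monitor level); must be > 0 for
#'   Poisson noise.
#' @param seed Integer seed; Poisson draws are bit-reproducible for a
#'   given seed and leave the global RNG state untouched.
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(mode = c("none", "poisson"), counts_scale = 1e5,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "poisson") stopifnot(counts_scale > 0)
  structure(list(mode = mode, counts_scale = counts_scale,
                 seed = as.integer(seed)), class = "noise_spec")
}

# Run code with a private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Apply counting noise to an array of expected counts.
apply_noise <- function(expected, noise, seed_offset = 0L) {
  if (noise$mode == "none")
    return(list(intensity = expected, sigma = array(0, dim(as.array(expected)))))
  counts <- with_private_seed(noise$seed + seed_offset, {
    array(stats::rpois(length(expected), lambda = as.numeric(expected)),
          dim = dim(as.array(expected)))
  })
  list(intensity = counts, sigma = sqrt(pmax(counts, 1)))
}

# Smooth detector-efficiency profile; NULL means flat. A function of Q or a
# per-Q numeric vector is accepted.
efficiency_values <- function(q, efficiency) {
  e <- if (is.null(efficiency)) rep(1, length(q))
  else if (is.function(efficiency)) efficiency(q)
  else rep_len(as.numeric(efficiency), length(q))
  if (any(e <= 0)) stop("detector efficiency must be positive", call. = FALSE)
  e
}

#' Default synthetic detector-efficiency profile
#'
#' A mild, smooth Q dependence used by \code{\link{simulate_experiment}} so
#' that the vanadium efficiency correction has something real to undo.
#'
#' @param q Momentum transfer (1/A).
#' @return Efficiency factors (dimensionless, positive).
#' @export
default_efficiency <- function(q) 1 + 0.15 * cos(2.2 * q)

# Smooth low-amplitude empty-cell shape (per unit level), O(1) at level 1.
empty_cell_shape <- function(q, level) level * (1 + 0.25 * exp(-q))

#' Simulate an elastic fixed-window temperature scan
#'
#' Noiseless expected intensity at (Q, T) is
#' \code{amplitude * eff(Q) * (exp(-msd(T) Q^2 / c) + transmission * empty)}
#' with \code{c} the package Gaussian convention constant
#' (\code{\link{gauss_constant}}); free and hydration water contribute no
#' elastic intensity on this ~1 ns window (their quasi-elastic broadening
#' falls outside the sub-ueV resolution). Expected counts are
#' \code{counts_scale} times the shape; Poisson noise is applied when
#' requested and is seed-reproducible.
#'
#' @param model A \code{\link{sample_model}}.
#' @param instrument An \code{\link{instrument_config}} (no energy grid
#'   needed).
#' @param temperatures Scan temperatures (K), ascending; default 250--310 K
#'   in 5 K steps.
#' @param noise A \code{\link{noise_spec}}.
#' @param amplitude Overall scale factor.
#' @param efficiency Detector-efficiency profile (function, vector or
#'   \code{NULL} for flat).
#' @param empty_level Empty-cell background amplitude as a fraction of the
#'   sample scale (0 for none).
#' @param transmission Sample transmission in (0, 1].
#' @return An \code{\link{elastic_scan}} with \code{monitor} set to
#'   \code{counts_scale} per temperature.
#' @export
simulate_elastic_scan <- function(model, instrument,
                                  temperatures = seq(250, 310, by = 5),
                                  noise = noise_spec("none"),
                                  amplitude = 1, efficiency = NULL,
                                  empty_level = 0, transmission = 1) {
  stopifnot(inherits(model, "sample_model"),
            inherits(instrument, "instrument_config"),
            length(temperatures) >= 1)
  q <- q_grid(instrument)
  eff <- efficiency_values(q, efficiency)
  msd <- msd_of_T(model, temperatures)
  shape <- exp(-outer(q^2, msd) / gauss_constant())      # n_q x n_T
  bg <- empty_cell_shape(q, empty_level)
  expected <- noise$counts_scale * amplitude * eff *
    (shape + transmission * bg)
  nz <- apply_noise(expected, noise)
  elastic_scan(q, temperatures, nz$intensity, nz$sigma,
               monitor = rep(noise$counts_scale, length(temperatures)),
               transmission = transmission,
               metadata = new_metadata(sample = model$name,
                                       instrument = instrument$name))
}

# Expected QENS spectral density (1/ueV) per (Q, omega) for a sample model:
# immobile (resolution-shaped) + hydration and free water Lorentzians
# convolved with the Gaussian resolution.
qens_density <- function(model, instrument, width_model = "jump") {
  q <- q_grid(instrument)
  omega <- omega_grid(instrument)
  sig <- resolution_sigma(instrument)
  tau_h <- if (width_model == "jump") model$tau_hyd else 0
  tau_f <- if (width_model == "jump") model$tau_free else 0
  dens <- matrix(0, length(q), length(omega))
  res_line <- gaussian_lineshape(omega, sig)
  for (i in seq_along(q)) {
    g_h <- jump_diffusion_hwhm(q[i], model$d_hyd, tau_h)
    g_f <- jump_diffusion_hwhm(q[i], model$d_free, tau_f)
    dens[i, ] <- model$immobile_fraction * res_line +
      model$p_hyd * convolve_lorentzian_gaussian(omega, g_h, sig) +
      model$p_free * convolve_lorentzian_gaussian(omega, g_f, sig)
  }
  list(q = q, omega = omega, density = dens, sigma_res = sig)
}

#' Simulate a quasi-elastic spectrum set
#'
#' Noiseless spectral density per (Q, omega) is
#' \code{F_imm * R(omega) + p_hyd * L(G_hyd) x R + p_free * L(G_free) x R}
#' plus a flat empty-cell background; \code{R} is the Gaussian resolution
#' lineshape of the instrument FWHM, \code{L} an area-normalized
#' Lorentzian, and the Lorentzian widths follow the jump-diffusion law
#' \code{G(Q) = hbar D Q^2 / (1 + D Q^2 tau)} (in ueV). The convolution is
#' performed numerically on an internally extended, refined grid; the
#' immobile component is the resolution lineshape itself. Densities are
#' converted to expected counts so that a pure-elastic peak bin collects
#' \code{counts_scale} counts.
#'
#' @inheritParams simulate_elastic_scan
#' @param temperature Sample temperature (K); quasi-elastic spectra in this
#'   study are taken at 298 K.
#' @param width_model \code{"jump"} (default) or \code{"fickian"}
#'   (\code{tau = 0}).
#' @return A \code{\link{spectrum_set}}. If the energy window is narrower
#'   than 3x the broadest Lorentzian at \code{q_max}, a truncation-risk
#'   warning is recorded in the metadata.
#' @export
simulate_qens <- function(model, instrument, temperature = 298,
                          noise = noise_spec("none"),
                          amplitude = 1, efficiency = NULL,
                          empty_level = 0, transmission = 1,
                          width_model = c("jump", "fickian")) {
  stopifnot(inherits(model, "sample_model"),
            inherits(instrument, "instrument_config"))
  width_model <- match.arg(width_model)
  if (is.null(instrument$energy_window))
    stop("instrument '", instrument$name, "' defines no energy grid",
         call. = FALSE)
  dn <- qens_density(model, instrument, width_model)
  eff <- efficiency_values(dn$q, efficiency)
  # counts conversion: unit-shape (elastic peak) bin -> counts_scale
  peak_ref <- gaussian_lineshape(0, dn$sigma_res)
  bg_density <- empty_cell_shape(dn$q, empty_level) * peak_ref
  expected <- noise$counts_scale * amplitude * eff *
    (dn$density + transmission * bg_density) / peak_ref
  nz <- apply_noise(expected, noise)
  md <- new_metadata(sample = model$name, instrument = instrument$name)
  g_max <- jump_diffusion_hwhm(instrument$q_max, model$d_free,
                               if (width_model == "jump") model$tau_free else 0)
  if (instrument$energy_window < 3 * g_max)
    md$warnings <- sprintf(
      "energy window %g ueV < 3x broadest Lorentzian HWHM %.3g ueV: truncation risk",
      instrument$energy_window, g_max)
  spectrum_set(dn$q, dn$omega, nz$intensity, nz$sigma,
               temperature = temperature, monitor = noise$counts_scale,
               transmission = transmission, metadata = md)
}

#' Simulate a vanadium calibration run
#'
#' Vanadium is a purely elastic, incoherent scatterer: its expected signal
#' is constant in Q up to the detector-efficiency profile.
#'
#' @inheritParams simulate_elastic_scan
#' @param v0 Intrinsic vanadium level (unit-shape scale).
#' @return A \code{\link{vanadium_ref}}.
#' @export
simulate_vanadium <- function(instrument, noise = noise_spec("none"),
                              efficiency = NULL, v0 = 1) {
  q <- q_grid(instrument)
  eff <- efficiency_values(q, efficiency)
  expected <- noise$counts_scale * v0 * eff
  nz <- apply_noise(expected, noise, seed_offset = 1L)
  vanadium_ref(q, nz$intensity, nz$sigma,
               metadata = new_metadata(sample = "vanadium",
                                       instrument = instrument$name))
}

#' Simulate an empty-cell background run
#'
#' A smooth, low-amplitude background at \code{level} times the sample
#' scale, shaped to match the sample dataset it will be subtracted from
#' (constant across T for elastic scans, flat in omega for QENS).
#'
#' @inheritParams simulate_elastic_scan
#' @param level Background amplitude as a fraction of sample scale, in
#'   [0, 0.5].
#' @param kind \code{"elastic"} or \code{"qens"}.
#' @param temperature QENS sample temperature (K).
#' @return An \code{\link{elastic_scan}} or \code{\link{spectrum_set}}.
#' @export
simulate_empty_cell <- function(instrument, level,
                                noise = noise_spec("none"),
                                kind = c("elastic", "qens"),
                                temperatures = seq(250, 310, by = 5),
                                temperature = 298, efficiency = NULL) {
  kind <- match.arg(kind)
  stopifnot(level >= 0, level <= 0.5)
  q <- q_grid(instrument)
  eff <- efficiency_values(q, efficiency)
  md <- new_metadata(sample = "empty_cell", instrument = instrument$name)
  if (kind == "elastic") {
    shape <- matrix(empty_cell_shape(q, level) * eff, length(q),
                    length(temperatures))
    expected <- noise$counts_scale * shape
    nz <- apply_noise(expected, noise, seed_offset = 2L)
    elastic_scan(q, temperatures, nz$intensity, nz$sigma,
                 monitor = rep(noise$counts_scale, length(temperatures)),
                 transmission = 1, metadata = md)
  } else {
    omega <- omega_grid(instrument)
    shape <- matrix(empty_cell_shape(q, level) * eff, length(q),
                    length(omega))
    expected <- noise$counts_scale * shape
    nz <- apply_noise(expected, noise, seed_offset = 2L)
    spectrum_set(q, omega, nz$intensity, nz$sigma,
                 temperature = temperature, monitor = noise$counts_scale,
                 transmission = 1, metadata = md)
  }
}

#' Simulate a complete measurement (sample + empty cell + vanadium)
#'
#' Convenience wrapper producing the three raw datasets a reduction needs,
#' sharing one detector-efficiency profile so the vanadium correction is
#' exercised for real.
#'
#' @inheritParams simulate_elastic_scan
#' @inheritParams simulate_empty_cell
#' @param kind \code{"elastic"} or \code{"qens"}.
#' @return List with elements \code{sample}, \code{empty}, \code{vanadium}.
#' @export
simulate_experiment <- function(model, instrument, kind = c("elastic", "qens"),
                                noise = noise_spec("none"),
                                temperatures = seq(250, 310, by = 5),
                                temperature = 298,
                                efficiency = default_efficiency,
                                empty_level = 0.05, transmission = 0.93) {
  kind <- match.arg(kind)
  sample <- if (kind == "elastic")
    simulate_elastic_scan(model, instrument, temperatures, noise,
                          efficiency = efficiency, empty_level = empty_level,
                          transmission = transmission)
  else
    simulate_qens(model, instrument, temperature, noise,
                  efficiency = efficiency, empty_level = empty_level,
                  transmission = transmission)
  empty <- simulate_empty_cell(instrument, empty_level, noise, kind,
                               temperatures = temperatures,
                               temperature = temperature,
                               efficiency = efficiency)
  vanadium <- simulate_vanadium(instrument, noise, efficiency = efficiency)
  list(sample = sample, empty = empty, vanadium = vanadium)
}
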