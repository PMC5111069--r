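#' Generative sample model (ground truth for synthetic spectra)
#'
#' Describes a hydrated ribosomal-subunit sample by the quantities the two
#' experiments probe: on the ~10 ps quasi-elastic timescale, an immobile
#' hydrogen fraction plus two diffusive water populations (free and
#' hydration water, each jump-diffusing with its own diffusion coefficient
#' and residence time); on the ~1 ns elastic-window timescale, a
#' piecewise-linear mean square displacement MSD(T) with a kink near the
#' free-water freezing temperature, anchored so that the line above the
#' kink passes through \code{msd_ref} at 310.15 K (37 C).
#'
#' @param name Sample label.
#' @param water_fraction Water mass fraction of the sample.
#' @param immobile_fraction Fraction of H atoms too slow to resolve on the
#'   ~10 ps timescale, in [0, 1].
#' @param p_hyd,p_free Hydration- and free-water population fractions;
#'   \code{immobile_fraction + p_hyd + p_free} must equal 1.
#' @param d_free,d_hyd Diffusion coefficients in A^2/ps.
#' @param tau_free,tau_hyd Jump-diffusion residence times in ps.
#' @param msd_ref MSD (A^2) at the 310.15 K reference temperature,
#'   evaluated on the above-kink line.
#' @param slope_above MSD slope (A^2/K) above the kink.
#' @param slope_below MSD slope (A^2/K) at and below the kink.
#' @param t_kink Kink temperature (K); default 273.
#' @return An object of class \code{sample_model}.
#' @export
sample_model <- function(name, water_fraction, immobile_fraction,
                         p_hyd, p_free,
                         d_free = 0.23, tau_free = 1.1,
                         d_hyd = 0.05, tau_hyd = 5.0,
                         msd_ref, slope_above,
                         slope_below = slope_above / 4, t_kink = 273) {
  fr <- c(immobile_fraction, p_hyd, p_free)
  stopifnot(all(fr >= 0), all(fr <= 1))
  if (abs(sum(fr) - 1) > 1e-8)
    stop("immobile_fraction + p_hyd + p_free must sum to 1", call. = FALSE)
  stopifnot(water_fraction >= 0, water_fraction <= 1,
            d_free > 0, d_hyd > 0, tau_free >= 0, tau_hyd >= 0,
            msd_ref >= 0, slope_above >= 0, slope_below >= 0)
  m <- structure(list(name = name, water_fraction = water_fraction,
                      immobile_fraction = immobile_fraction,
                      p_hyd = p_hyd, p_free = p_free,
                      d_free = d_free, tau_free = tau_free,
                      d_hyd = d_hyd, tau_hyd = tau_hyd,
                      msd_ref = msd_ref, slope_above = slope_above,
                      slope_below = slope_below, t_kink = t_kink),
                 class = "sample_model")
  if (msd_of_T(m, 200) < 0)
    stop("model MSD is negative within the 200-350 K range", call. = FALSE)
  m
}

#' @export
print.sample_model <- function(x, ...) {
  cat(sprintf("<sample_model> %s: %.0f%% water, immobile %.1f%%\n",
              x$name, 100 * x$water_fraction, 100 * x$immobile_fraction))
  cat(sprintf("  water: free D=%.3g A^2/ps tau=%.3g ps (%.1f%%), hydration D=%.3g tau=%.3g (%.1f%%)\n",
              x$d_free, x$tau_free, 100 * x$p_free,
              x$d_hyd, x$tau_hyd, 100 * x$p_hyd))
  cat(sprintf("  MSD: %.3g A^2 at 310.15 K, slopes %.4g / %.4g A^2/K, kink %g K\n",
              x$msd_ref, x$slope_above, x$slope_below, x$t_kink))
  invisible(x)
}

#' Piecewise-linear mean square displacement of a sample model
#'
#' Continuous at the kink; for T above the kink the slope is
#' \code{slope_above} and the line passes through \code{msd_ref} at
#' 310.15 K.
#'
#' @param model A \code{sample_model}.
#' @param temperature Temperature(s) in K, within 200--350.
#' @return MSD in A^2 (vectorized over \code{temperature}).
#' @export
msd_of_T <- function(model, temperature) {
  stopifnot(inherits(model, "sample_model"))
  if (any(temperature < 200 | temperature > 350))
    stop("temperature outside the supported 200-350 K range", call. = FALSE)
  msd_kink <- model$msd_ref - model$slope_above * (T_REF_K - model$t_kink)
  dT <- temperature - model$t_kink
  msd <- msd_kink + ifelse(dT > 0, model$slope_above * dT,
                           model$slope_below * dT)
  if (any(msd < 0))
    stop("model MSD is negative at the requested temperature(s)", call. = FALSE)
  msd
}

#' Built-in fixture catalog
#'
#' Three sample models for hydrated Haloarcula marismortui ribosomal
#' subunits in 3 M salt, the ground truth behind every synthetic fixture:
#' \code{h30s_nacl} (30S subunit, 3 M NaCl), \code{h30s_kcl} (30S, 3 M KCl)
#' and \code{h50s_nacl} (50S, 3 M NaCl). Immobile fractions, water
#' contents, MSD at 37 C and force constants (encoded as
#' \code{slope_above = 0.002761 / k}) are set from the reported study
#' values; no immobile fraction is reported for the KCl condition, so it
#' reuses the NaCl value. The water-population split and the diffusion
#' parameters are synthetic, literature-scale choices (bulk-like free
#' water, several-fold slower hydration water); the hydration share of the
#' mobile water is set slightly higher for NaCl than KCl, and highest for
#' the 50S sample, mirroring the reported relative water-binding trends.
#'
#' @return Named list of three \code{sample_model} objects.
#' @export
fixture_catalog <- function() {
  mk <- function(name, water, f_imm, hyd_share, msd_ref, k) {
    sample_model(name, water_fraction = water, immobile_fraction = f_imm,
                 p_hyd = hyd_share * (1 - f_imm),
                 p_free = (1 - hyd_share) * (1 - f_imm),
                 msd_ref = msd_ref, slope_above = QH_CONST / k)
  }
  list(
    h30s_nacl = mk("h30s_nacl", 0.65, 0.063, 0.35, 17.9, 0.016),
    h30s_kcl  = mk("h30s_kcl",  0.62, 0.063, 0.30, 16.3, 0.018),
    h50s_nacl = mk("h50s_nacl", 0.67, 0.093, 0.40, 12.1, 0.034)
  )
}
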