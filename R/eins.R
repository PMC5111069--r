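# Elastic-scan analysis: Gaussian-approximation MSD extraction per
# temperature, above-kink linear fit of MSD(T), quasi-harmonic effective
# force constant, and piecewise-linear kink detection.

# Weighted least squares with known weights: no residual-variance rescaling,
# the covariance is solve(X'WX) (first-order propagation of the supplied
# sigmas). Falls back to unit weights when no usable sigmas are provided.
wls_fit <- function(X, y, w) {
  if (all(w == 0) || !any(is.finite(w) & w > 0)) w <- rep(1, length(y))
  XtW <- t(X * w)
  cov <- solve(XtW %*% X)
  beta <- drop(cov %*% (XtW %*% y))
  res <- y - drop(X %*% beta)
  list(beta = beta, cov = cov, chisq = sum(w * res^2),
       df = length(y) - ncol(X))
}

#' Extract mean square displacements from an elastic scan
#'
#' For each temperature, fits the semi-logarithmic Gaussian approximation
#' \code{ln S_el = intercept - msd * Q^2 / c} by weighted least squares
#' over the chosen Q window (weights from first-order propagation,
#' \code{sigma_ln = sigma / I}); the MSD is \code{-c} times the slope, with
#' \code{c} the shared convention constant (\code{\link{gauss_constant}}).
#' Non-positive intensities are dropped with a warning. The
#' Gaussian-approximation validity flag is set per temperature when
#' \code{msd * q_hi^2 <= 4}; exceeding 4 is reported as a warning, not an
#' error, since the large-MSD samples studied here routinely do.
#'
#' @param scan A reduced \code{\link{elastic_scan}}.
#' @param q_window Q window (1/A), closed interval; the study's standard
#'   window is 0.34--0.85.
#' @return An object of class \code{msd_series}: a data frame with columns
#'   \code{temperature}, \code{msd}, \code{msd_sigma}, \code{intercept},
#'   \code{chisq}, \code{gauss_valid}, with the Q window and convention
#'   constant as attributes.
#' @export
fit_msd <- function(scan, q_window = c(0.34, 0.85)) {
  stopifnot(inherits(scan, "elastic_scan"), length(q_window) == 2L)
  sub <- restrict_q(scan, q_window[1], q_window[2])
  if (length(sub$q) < 3)
    stop("need >= 3 Q points in the window; got ", length(sub$q),
         call. = FALSE)
  cc <- gauss_constant()
  q2 <- sub$q^2
  n_dropped <- 0L
  out <- lapply(seq_along(sub$temperatures), function(j) {
    I <- sub$intensity[, j]; s <- sub$sigma[, j]
    ok <- I > 0
    n_dropped <<- n_dropped + sum(!ok)
    if (sum(ok) < 3)
      stop(sprintf("fewer than 3 usable Q points at T = %g K",
                   sub$temperatures[j]), call. = FALSE)
    x <- q2[ok]; y <- log(I[ok])
    w <- if (all(s[ok] == 0)) rep(1, sum(ok)) else (I[ok] / s[ok])^2
    f <- wls_fit(cbind(1, x), y, w)
    msd <- unname(-cc * f$beta[2])
    data.frame(temperature = sub$temperatures[j], msd = msd,
               msd_sigma = cc * sqrt(f$cov[2, 2]),
               intercept = unname(f$beta[1]), chisq = f$chisq,
               gauss_valid = msd * q_window[2]^2 <= 4)
  })
  if (n_dropped > 0)
    warning(n_dropped, " non-positive intensity value(s) dropped from the ",
            "semi-log fits", call. = FALSE)
  res <- do.call(rbind, out)
  if (any(!res$gauss_valid))
    warning("msd * q_hi^2 exceeds 4 at ", sum(!res$gauss_valid),
            " temperature(s): Gaussian approximation stretched", call. = FALSE)
  structure(res, q_window = q_window, convention = cc,
            class = c("msd_series", "data.frame"))
}

#' Radius of gyration of the motion from an MSD series
#'
#' Returns \code{msd / 2}, i.e. \code{R_g^2} of the motion about its
#' center (the full MSD equals twice the squared radius of gyration).
#'
#' @param series An \code{msd_series}.
#' @return Numeric vector of R_g^2 values in A^2.
#' @export
rg_squared <- function(series) {
  stopifnot(inherits(series, "msd_series"))
  series$msd / 2
}

#' Effective force constant from the MSD temperature dependence
#'
#' Weighted straight-line fit of MSD versus T restricted to
#' \code{T > t_min}; in the quasi-harmonic approximation the resilience is
#' \code{<k> = 0.002761 / slope} (N/m when the MSD is in A^2 and T in K),
#' with \code{sigma_k = <k> * sigma_slope / slope}. The MSD at the 37 C
#' reference (310.15 K) is evaluated on the fitted line with its
#' propagated uncertainty.
#'
#' @param series An \code{msd_series}.
#' @param t_min Lower temperature bound (K) for the fit; points strictly
#'   above are used. Default 270 K.
#' @return An object of class \code{force_constant_result}: list with
#'   \code{slope}, \code{slope_sigma} (A^2/K), \code{k_eff},
#'   \code{k_sigma} (N/m; \code{NA} and \code{physical = FALSE} when the
#'   slope is non-positive), \code{msd_at_ref}, \code{msd_at_ref_sigma}
#'   (A^2 at 310.15 K), \code{t_min_fit} and \code{n_points_fit}.
#' @export
fit_force_constant <- function(series, t_min = 270) {
  stopifnot(inherits(series, "msd_series"))
  use <- series$temperature > t_min
  if (sum(use) < 3)
    stop("need >= 3 temperatures above t_min = ", t_min, " K; got ",
         sum(use), call. = FALSE)
  Tt <- series$temperature[use]; y <- series$msd[use]
  s <- series$msd_sigma[use]
  w <- if (all(s == 0)) rep(1, length(y)) else 1 / s^2
  f <- wls_fit(cbind(1, Tt), y, w)
  slope <- unname(f$beta[2]); slope_sigma <- sqrt(f$cov[2, 2])
  physical <- slope > 0
  k <- if (physical) QH_CONST / slope else NA_real_
  k_sigma <- if (physical) k * slope_sigma / slope else NA_real_
  xr <- c(1, T_REF_K)
  msd_ref <- sum(xr * f$beta)
  msd_ref_sigma <- sqrt(drop(t(xr) %*% f$cov %*% xr))
  structure(list(slope = slope, slope_sigma = slope_sigma,
                 t_min_fit = t_min, k_eff = k, k_sigma = k_sigma,
                 msd_at_ref = msd_ref, msd_at_ref_sigma = msd_ref_sigma,
                 n_points_fit = sum(use), physical = physical,
                 chisq = f$chisq, df = f$df),
            class = "force_constant_result")
}

#' @export
print.force_constant_result <- function(x, ...) {
  cat("<force_constant_result>\n")
  if (x$physical)
    cat(sprintf("  <k> = %.4g +/- %.2g N/m  (slope %.4g +/- %.2g A^2/K, T > %g K, n = %d)\n",
                x$k_eff, x$k_sigma, x$slope, x$slope_sigma, x$t_min_fit,
                x$n_points_fit))
  else
    cat("  non-physical fit (slope <= 0): <k> undefined\n")
  cat(sprintf("  MSD(310.15 K) = %.4g +/- %.2g A^2\n",
              x$msd_at_ref, x$msd_at_ref_sigma))
  invisible(x)
}

#' Locate the kink in an MSD temperature series
#'
#' Fits a continuous two-segment piecewise-linear model for every interior
#' candidate breakpoint (each measured temperature with at least 3 points
#' on each side) and returns the breakpoint minimizing the weighted sum of
#' squared errors; ties are broken toward the lower temperature. In these
#' samples the kink near 273 K marks the stiffening that accompanies
#' freezing of free water.
#'
#' @param series An \code{msd_series} with at least 6 temperatures.
#' @return The breakpoint temperature (K), with the per-candidate SSE
#'   table as attribute \code{"sse"}.
#' @export
detect_kink <- function(series) {
  stopifnot(inherits(series, "msd_series"))
  Tt <- series$temperature; y <- series$msd; s <- series$msd_sigma
  if (length(Tt) < 6)
    stop("need >= 6 temperatures to locate a kink", call. = FALSE)
  w <- if (all(s == 0)) rep(1, length(y)) else 1 / s^2
  cand <- Tt[vapply(Tt, function(tc)
    sum(Tt <= tc) >= 3 && sum(Tt >= tc) >= 3, logical(1))]
  if (!length(cand))
    stop("no candidate breakpoint leaves 3 points per segment", call. = FALSE)
  sse <- vapply(cand, function(tc) {
    X <- cbind(1, Tt - tc, pmax(Tt - tc, 0))
    f <- wls_fit(X, y, w)
    f$chisq
  }, numeric(1))
  tol <- 1e-8 * (min(sse) + max(abs(y))^2 * 1e-8) + 1e-12
  eligible <- which(sse <= min(sse) + tol)
  kink <- cand[min(eligible)]
  attr(kink, "sse") <- data.frame(candidate = cand, sse = sse)
  kink
}
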