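# Quasi-elastic analysis: per-Q resolution-convolved delta + two-Lorentzian
# fits, jump-diffusion dispersion fits of the widths, immobile-fraction
# estimation, and binned unit-area comparison spectra.
#
# The immobile fraction reported by fit_qens comes from a second,
# width-constrained pass: with the two Lorentzian widths pinned to the
# fitted dispersion laws, the per-Q amplitude fit is linear and
# well-conditioned at every Q, so the elastic/quasi-elastic split is
# unbiased even where a free fit is degenerate (narrow width far below
# the resolution, or broad width rivaling the energy window).

pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  d <- s$d
  pos <- d > tol * max(d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / d[pos])
}

# Invert a symmetric normal matrix after rescaling to unit diagonal, so
# wildly different parameter scales (amplitudes vs widths) cannot push
# genuine directions below a relative tolerance. Near-singular directions
# get a tiny ridge: their variance comes out honestly enormous instead of
# silently truncated to zero.
sym_inv_scaled <- function(M) {
  d <- sqrt(pmax(diag(M), 0))
  d[d == 0] <- 1
  Ms <- M / outer(d, d)
  inv_s <- tryCatch(solve(Ms), error = function(e)
    solve(Ms + diag(1e-10, nrow(Ms))))
  inv_s / outer(d, d)
}

# numerical Jacobian of a residual function at a point
num_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (k in seq_along(par)) {
    h <- eps * max(abs(par[k]), 1e-3)
    pp <- par; pp[k] <- pp[k] + h
    J[, k] <- (fn(pp) - r0) / h
  }
  J
}

# delta + two Lorentzians convolved with Gaussian resolution, flat background
qens_model <- function(par, omega, sigma_res) {
  par["a0"] * gaussian_lineshape(omega, sigma_res) +
    par["a1"] * voigt_profile(omega, sigma_res, par["g1"]) +
    par["a2"] * voigt_profile(omega, sigma_res, par["g2"]) +
    par["b"]
}

#' Fit one Q slice of a quasi-elastic spectrum
#'
#' Weighted nonlinear least squares of
#' \code{a0 R(w) + a1 L(G1) x R + a2 L(G2) x R + b} against the measured
#' spectrum at one Q; \code{R} is the Gaussian resolution lineshape and
#' the Lorentzian convolutions are evaluated in closed form as Voigt
#' profiles. Amplitudes are bounded below by zero and widths confined to
#' \code{(0, energy window]}. Initialization is a deterministic multi-start
#' over a coarse grid of width pairs (amplitudes seeded by weighted linear
#' least squares at fixed widths). If the two widths converge within 10%
#' of each other the fit is re-run with a single Lorentzian and flagged.
#'
#' A slice whose narrow width comes out below a tenth of the resolution
#' sigma is flagged \code{degenerate}: such a Lorentzian is unresolvable
#' against the elastic line and its amplitude split is arbitrary, so
#' downstream estimators skip the slice.
#'
#' @param spec A reduced \code{\link{spectrum_set}}.
#' @param q The Q value to fit (must match a grid point).
#' @param sigma_res Gaussian resolution standard deviation (ueV), e.g.
#'   \code{fwhm_to_sigma(75)} or the result of \code{\link{fit_resolution}}.
#' @return A one-row data frame with amplitudes \code{a0, a1, a2},
#'   background \code{b}, widths \code{gamma1 <= gamma2} (ueV), their
#'   uncertainties, goodness of fit (\code{chisq}, \code{redchi}),
#'   \code{single}, \code{degenerate} and \code{converged} flags, and the
#'   amplitude covariance as attribute \code{"acov"}.
#' @export
fit_spectrum_q <- function(spec, q, sigma_res) {
  stopifnot(inherits(spec, "spectrum_set"), sigma_res > 0)
  i <- which(abs(spec$q - q) < 1e-9)
  if (length(i) != 1)
    stop("q = ", q, " is not a grid point of the spectrum", call. = FALSE)
  omega <- spec$omega
  y <- spec$intensity[i, ]; s <- spec$sigma[i, ]
  if (all(s == 0)) s <- rep(1, length(y)) else s <- pmax(s, max(s) * 1e-6)
  W <- spec$omega[length(omega)]
  gmin <- W * 1e-5

  lin_init <- function(g1, g2) {
    X <- cbind(gaussian_lineshape(omega, sigma_res),
               voigt_profile(omega, sigma_res, g1),
               voigt_profile(omega, sigma_res, g2), 1)
    beta <- tryCatch(drop(pinv(t(X / s^2) %*% X) %*% (t(X / s^2) %*% y)),
                     error = function(e) rep(NA_real_, 4))
    amax <- max(sum(y) * diff(range(omega)) / length(omega), 1e-12)
    a <- pmax(beta[1:3], amax * 1e-4)
    a[!is.finite(a)] <- amax * 1e-2
    b <- beta[4]; if (!is.finite(b)) b <- 0
    c(a0 = a[1], a1 = a[2], a2 = a[3], g1 = g1, g2 = g2, b = b)
  }

  starts <- list(c(sigma_res / 4, sigma_res), c(sigma_res / 2, 4 * sigma_res),
                 c(sigma_res, 8 * sigma_res), c(sigma_res / 8, 2 * sigma_res),
                 c(2 * sigma_res, W / 3))
  starts <- lapply(starts, function(g) pmin(pmax(g, 2 * gmin), W))
  resid_fn <- function(par) (qens_model(par, omega, sigma_res) - y) / s
  lower <- c(0, 0, 0, gmin, gmin, -Inf)
  upper <- c(Inf, Inf, Inf, W, W, Inf)

  best <- NULL; diagnostics <- character()
  for (g in starts) {
    p0 <- lin_init(g[1], g[2])
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) { diagnostics <- c(diagnostics, "nls.lm error"); next }
    if (!fit$info %in% 1:4) {
      diagnostics <- c(diagnostics, paste0("info=", fit$info, ": ", fit$message))
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("QENS fit did not converge from any start at Q = ", spec$q[i],
         "; diagnostics: ", paste(unique(diagnostics), collapse = "; "),
         call. = FALSE)

  par <- best$par
  # enforce gamma1 <= gamma2
  if (par["g1"] > par["g2"]) {
    par[c("a1", "a2")] <- par[c("a2", "a1")]
    par[c("g1", "g2")] <- par[c("g2", "g1")]
  }
  single <- (par["g2"] - par["g1"]) < 0.1 * par["g2"]

  if (single) {
    resid1 <- function(p) {
      pp <- c(a0 = unname(p[1]), a1 = unname(p[2]), a2 = 0,
              g1 = unname(p[3]), g2 = W, b = unname(p[4]))
      (qens_model(pp, omega, sigma_res) - y) / s
    }
    p1 <- c(par["a0"], par["a1"] + par["a2"], mean(par[c("g1", "g2")]),
            par["b"])
    fit1 <- minpack.lm::nls.lm(p1, lower = c(0, 0, gmin, -Inf),
                               upper = c(Inf, Inf, W, Inf), fn = resid1,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
    par <- c(a0 = unname(fit1$par[1]), a1 = unname(fit1$par[2]), a2 = 0,
             g1 = unname(fit1$par[3]), g2 = NA_real_, b = unname(fit1$par[4]))
    J <- num_jacobian(resid1, fit1$par)
    covp <- sym_inv_scaled(t(J) %*% J)
    dev <- fit1$deviance
    df <- length(y) - 4L
    infl <- max(1, dev / max(df, 1))
    se <- sqrt(pmax(diag(covp), 0) * infl)
    sigmas <- c(a0 = se[1], a1 = se[2], a2 = 0, g1 = se[3], g2 = NA_real_,
                b = se[4])
    acov <- matrix(0, 3, 3)
    acov[1:2, 1:2] <- covp[1:2, 1:2] * infl
  } else {
    J <- num_jacobian(resid_fn, par)
    covp <- sym_inv_scaled(t(J) %*% J)
    dev <- best$deviance
    df <- length(y) - 6L
    infl <- max(1, dev / max(df, 1))
    se <- sqrt(pmax(diag(covp), 0) * infl)
    sigmas <- stats::setNames(se, names(par))
    acov <- covp[1:3, 1:3] * infl
  }

  rec <- data.frame(q = spec$q[i],
                    a0 = unname(par["a0"]), a1 = unname(par["a1"]),
                    a2 = unname(par["a2"]), b = unname(par["b"]),
                    a0_sigma = unname(sigmas["a0"]),
                    a1_sigma = unname(sigmas["a1"]),
                    a2_sigma = unname(sigmas["a2"]),
                    gamma1 = unname(par["g1"]), gamma2 = unname(par["g2"]),
                    gamma1_sigma = unname(sigmas["g1"]),
                    gamma2_sigma = unname(sigmas["g2"]),
                    chisq = dev, redchi = dev / max(df, 1),
                    single = unname(single),
                    degenerate = unname(
                      (par["a1"] > 0.01 * sum(par[c("a0", "a1", "a2")]) &
                         is.finite(par["g1"]) & par["g1"] < sigma_res / 10) |
                        (is.finite(par["g2"]) & par["g2"] > 0.5 * W)),
                    converged = TRUE)
  attr(rec, "acov") <- acov
  rec
}

#' Fit the Gaussian resolution width from a vanadium spectrum
#'
#' Weighted fit of \code{A R(w; sigma) + b} to a measured vanadium
#' quasi-elastic spectrum (summed over Q), returning the Gaussian sigma.
#'
#' @param spec A \code{\link{spectrum_set}} of a vanadium (purely elastic)
#'   measurement.
#' @param sigma0 Starting value for sigma (ueV); defaults to a tenth of
#'   the energy window.
#' @return Fitted Gaussian standard deviation in ueV.
#' @export
fit_resolution <- function(spec, sigma0 = NULL) {
  stopifnot(inherits(spec, "spectrum_set"))
  omega <- spec$omega
  y <- colSums(spec$intensity)
  s <- sqrt(colSums(spec$sigma^2)); if (all(s == 0)) s <- rep(1, length(y))
  if (is.null(sigma0)) sigma0 <- diff(range(omega)) / 20
  A0 <- max(sum(y) * mean(diff(omega)), 1e-12)
  fit <- minpack.lm::nls.lm(
    c(A = A0, sigma = sigma0, b = min(y)),
    lower = c(0, 1e-6, -Inf),
    fn = function(p) (p["A"] * gaussian_lineshape(omega, p["sigma"]) +
                        p["b"] - y) / s)
  unname(fit$par["sigma"])
}

#' Fit the jump-diffusion dispersion of Lorentzian widths
#'
#' Weighted fit of \code{Gamma(Q) = hbar D Q^2 / (1 + D Q^2 tau)} to a
#' table of per-Q half-widths. If the residence time collapses onto its
#' lower bound the fit falls back to the Fickian law (\code{tau = 0}).
#'
#' After the first fit, points whose residuals exceed \code{trim} robust
#' standard deviations are dropped once and the law re-fitted, so isolated
#' per-Q failures cannot drag the dispersion off.
#'
#' @param q Momentum transfers (1/A), at least 4.
#' @param gamma Lorentzian HWHMs (ueV).
#' @param gamma_sigma Their uncertainties (ueV); zeros give unit weights.
#' @param trim Outlier threshold in robust standard deviations
#'   (\code{Inf} to disable).
#' @return List with \code{d}, \code{d_sigma} (A^2/ps), \code{tau},
#'   \code{tau_sigma} (ps) and the \code{model} used
#'   (\code{"jump"} or \code{"fickian"}).
#' @export
fit_dispersion <- function(q, gamma, gamma_sigma = rep(0, length(q)),
                           trim = 3) {
  ok <- is.finite(gamma) & is.finite(q)
  q <- q[ok]; gamma <- gamma[ok]; gamma_sigma <- gamma_sigma[ok]
  if (length(q) < 4)
    stop("need >= 4 Q points with finite widths; got ", length(q),
         call. = FALSE)
  s <- if (all(gamma_sigma == 0) || any(!is.finite(gamma_sigma)))
    rep(1, length(q)) else pmax(gamma_sigma, max(gamma_sigma) * 1e-6)
  d0 <- max(gamma[which.min(q)] / (HBAR_UEV_PS * min(q)^2), 1e-4)
  tau0 <- max(HBAR_UEV_PS / max(gamma) * 0.5, 1e-3)
  resid <- function(p) (jump_diffusion_hwhm(q, p["d"], p["tau"]) - gamma) / s
  fit <- minpack.lm::nls.lm(c(d = d0, tau = tau0),
                            lower = c(1e-8, 0), upper = c(Inf, Inf),
                            fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  # one outlier-trimming pass: gross per-Q width failures (local minima of
  # the free fits) would otherwise drag the dispersion law off
  if (is.finite(trim) && trim > 0) {
    r <- resid(fit$par)
    scale <- max(stats::mad(r, center = 0), 1e-12)
    keep <- abs(r) <= trim * scale
    if (any(!keep) && sum(keep) >= 4) {
      q <- q[keep]; gamma <- gamma[keep]; s <- s[keep]
      resid <- function(p) (jump_diffusion_hwhm(q, p["d"], p["tau"]) - gamma) / s
      fit <- minpack.lm::nls.lm(fit$par, lower = c(1e-8, 0),
                                upper = c(Inf, Inf), fn = resid,
                                control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  model <- "jump"
  if (fit$par["tau"] < 1e-6) {
    model <- "fickian"
    residf <- function(p) (HBAR_UEV_PS * p["d"] * q^2 - gamma) / s
    fit <- minpack.lm::nls.lm(c(d = d0), lower = 1e-8, fn = residf)
  }
  fn <- if (model == "jump") resid else
    function(p) (HBAR_UEV_PS * p["d"] * q^2 - gamma) / s
  J <- num_jacobian(fn, fit$par)
  covp <- sym_inv_scaled(t(J) %*% J) * max(1, fit$deviance / max(length(q) - length(fit$par), 1))
  se <- sqrt(pmax(diag(covp), 0))
  list(d = unname(fit$par["d"]), d_sigma = se[1],
       tau = if (model == "jump") unname(fit$par["tau"]) else 0,
       tau_sigma = if (model == "jump") se[2] else 0,
       model = model)
}

#' Immobile hydrogen fraction from per-Q QENS fits
#'
#' Per Q, the elastic fraction is \code{a0 / (a0 + a1 + a2)} with its
#' uncertainty from the amplitude covariance (delta method); the overall
#' estimate is the inverse-variance-weighted mean over the valid
#' (converged, non-degenerate) fits. Single-Lorentzian slices contribute
#' with \code{a2 = 0}.
#'
#' @param records A data frame of per-Q fit records as returned by
#'   \code{\link{fit_spectrum_q}} / \code{\link{fit_qens}}, with the per-Q
#'   amplitude covariances in attribute \code{"acov_list"} (or a list of
#'   one-row records).
#' @return List with \code{fraction}, \code{sigma} and the per-Q table
#'   (\code{per_q}) retained for Q-dependence diagnostics.
#' @export
immobile_fraction <- function(records) {
  if (is.data.frame(records)) {
    acovs <- attr(records, "acov_list")
    recs <- split(records, seq_len(nrow(records)))
  } else {
    acovs <- lapply(records, attr, "acov")
    recs <- records
  }
  f <- numeric(0); fs <- numeric(0); qs <- numeric(0)
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    if (!isTRUE(r$converged) || isTRUE(r$degenerate)) next
    a <- c(r$a0, r$a1, r$a2); S <- sum(a)
    if (S <= 0) next
    grad <- c(S - a[1], -a[1], -a[1]) / S^2
    v <- drop(t(grad) %*% acovs[[k]] %*% grad)
    f <- c(f, a[1] / S); fs <- c(fs, sqrt(max(v, 0))); qs <- c(qs, r$q)
  }
  if (length(f) < 3)
    stop("fewer than 3 valid (two-Lorentzian, converged) fits: ",
         length(f), call. = FALSE)
  w <- if (all(fs == 0)) rep(1, length(f)) else 1 / fs^2
  est <- sum(w * f) / sum(w)
  sig <- if (all(fs == 0)) stats::sd(f) / sqrt(length(f)) else sqrt(1 / sum(w))
  list(fraction = est, sigma = sig,
       per_q = data.frame(q = qs, fraction = f, sigma = fs))
}

# Amplitude-only weighted linear fit of one Q slice with both Lorentzian
# widths fixed (e.g. to the dispersion-law prediction). Unbounded linear
# WLS: unbiased with an honest covariance even where the components are
# nearly collinear.
constrained_amplitudes <- function(spec, i, sigma_res, g1, g2) {
  omega <- spec$omega
  y <- spec$intensity[i, ]; s <- spec$sigma[i, ]
  if (all(s == 0)) s <- rep(1, length(y)) else s <- pmax(s, max(s) * 1e-6)
  X <- cbind(gaussian_lineshape(omega, sigma_res),
             voigt_profile(omega, sigma_res, g1),
             voigt_profile(omega, sigma_res, g2), 1)
  w <- 1 / s^2
  XtW <- t(X * w)
  cov <- sym_inv_scaled(XtW %*% X)
  beta <- drop(cov %*% (XtW %*% y))
  res <- y - drop(X %*% beta)
  infl <- max(1, sum(w * res^2) / max(length(y) - 4L, 1))
  list(a = beta[1:3], b = beta[4], acov = cov[1:3, 1:3] * infl,
       wres = res / s)
}

# Weighted residuals of the width-constrained amplitude fit at every Q,
# concatenated — the profile objective for dispersion refinement.
profile_residuals <- function(spec, sigma_res, d_h, tau_h, d_f, tau_f) {
  g1 <- jump_diffusion_hwhm(spec$q, d_h, tau_h)
  g2 <- jump_diffusion_hwhm(spec$q, d_f, tau_f)
  unlist(lapply(seq_along(spec$q), function(i)
    constrained_amplitudes(spec, i, sigma_res, g1[i], g2[i])$wres))
}

# Refine the four dispersion parameters by minimizing the pooled profile
# chi-square over all (Q, omega) points, per-Q amplitudes profiled out
# linearly. Log-parameterized for positivity; a small deterministic
# multi-start on the hydration parameters guards against the
# elastic/narrow local optimum the per-Q initialization can fall into.
refine_dispersion <- function(spec, sigma_res, disp_h, disp_f) {
  p0 <- c(d_h = disp_h$d, tau_h = max(disp_h$tau, 1e-3),
          d_f = disp_f$d, tau_f = max(disp_f$tau, 1e-3))
  objective <- function(lp) {
    p <- exp(lp)
    profile_residuals(spec, sigma_res, p[1], p[2], p[3], p[4])
  }
  scalings <- list(c(1, 1, 1, 1), c(0.5, 1, 1, 1),
                   c(0.25, 0.5, 1, 1), c(2, 2, 1, 1))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 50, epsfcn = 1e-8)
  best <- NULL
  for (sc in scalings) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(log(p0 * sc), fn = objective,
                                          control = ctrl)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) return(list(h = disp_h, f = disp_f, log_cov = NULL))
  p <- exp(best$par)
  J <- num_jacobian(objective, best$par, eps = 1e-5)
  covp <- sym_inv_scaled(t(J) %*% J) *
    max(1, best$deviance / max(length(objective(best$par)) - 4L, 1))
  se <- sqrt(pmax(diag(covp), 0)) * p      # delta method from log scale
  list(h = list(d = unname(p[1]), d_sigma = unname(se[1]),
                tau = unname(p[2]), tau_sigma = unname(se[2]),
                model = disp_h$model),
       f = list(d = unname(p[3]), d_sigma = unname(se[3]),
                tau = unname(p[4]), tau_sigma = unname(se[4]),
                model = disp_f$model),
       log_cov = covp)
}

# Immobile fraction from width-constrained amplitude fits at every Q.
constrained_immobile <- function(spec, sigma_res, disp_h, disp_f) {
  g1 <- jump_diffusion_hwhm(spec$q, disp_h$d, disp_h$tau)
  g2 <- jump_diffusion_hwhm(spec$q, disp_f$d, disp_f$tau)
  f <- fs <- numeric(length(spec$q))
  for (i in seq_along(spec$q)) {
    ca <- constrained_amplitudes(spec, i, sigma_res, g1[i], g2[i])
    S <- sum(ca$a)
    grad <- c(S - ca$a[1], -ca$a[1], -ca$a[1]) / S^2
    f[i] <- ca$a[1] / S
    fs[i] <- sqrt(max(drop(t(grad) %*% ca$acov %*% grad), 0))
  }
  w <- if (all(fs == 0)) rep(1, length(f)) else 1 / fs^2
  est <- sum(w * f) / sum(w)
  sig <- if (all(fs == 0)) stats::sd(f) / sqrt(length(f)) else sqrt(1 / sum(w))
  list(fraction = est, sigma = sig,
       per_q = data.frame(q = spec$q, fraction = f, sigma = fs))
}

#' Fit a full quasi-elastic spectrum set
#'
#' Runs \code{\link{fit_spectrum_q}} at every Q, fits the jump-diffusion
#' dispersion of the narrow (hydration-water) and broad (free-water)
#' widths over the valid slices, then re-fits the component amplitudes at
#' every Q with the widths pinned to the dispersion laws and estimates the
#' immobile fraction from that well-conditioned linear pass (falling back
#' to the free-fit amplitudes if a dispersion fit is unavailable).
#'
#' @param spec A reduced \code{\link{spectrum_set}}.
#' @param sigma_res Resolution sigma (ueV); alternatively give
#'   \code{instrument} to use its nominal FWHM, or \code{vanadium_spec}
#'   (a vanadium \code{spectrum_set}) to fit it.
#' @param instrument Optional \code{\link{instrument_config}}.
#' @param vanadium_spec Optional vanadium \code{spectrum_set}.
#' @return An object of class \code{qens_fit}: list with the per-Q record
#'   table (\code{records}), dispersion fits \code{hydration} and
#'   \code{free}, and \code{immobile} (fraction, sigma, per-Q table).
#' @export
fit_qens <- function(spec, sigma_res = NULL, instrument = NULL,
                     vanadium_spec = NULL) {
  if (is.null(sigma_res)) {
    sigma_res <- if (!is.null(vanadium_spec)) fit_resolution(vanadium_spec)
    else if (!is.null(instrument)) resolution_sigma(instrument)
    else stop("provide sigma_res, instrument or vanadium_spec", call. = FALSE)
  }
  recs <- lapply(spec$q, function(qq)
    tryCatch(fit_spectrum_q(spec, qq, sigma_res), error = function(e) NULL))
  keep <- !vapply(recs, is.null, logical(1))
  recs <- recs[keep]
  if (!length(recs)) stop("no Q slice could be fitted", call. = FALSE)
  tab <- do.call(rbind, recs)
  attr(tab, "acov_list") <- lapply(recs, attr, "acov")
  valid <- tab$converged & !tab$single & !tab$degenerate
  disp_h <- disp_f <- NULL
  if (sum(valid) >= 4) {
    disp_h <- tryCatch(fit_dispersion(tab$q[valid], tab$gamma1[valid],
                                      tab$gamma1_sigma[valid]),
                       error = function(e) NULL)
    disp_f <- tryCatch(fit_dispersion(tab$q[valid], tab$gamma2[valid],
                                      tab$gamma2_sigma[valid]),
                       error = function(e) NULL)
  }
  # dispersion-level refinement: the per-Q free fits cannot separate the
  # elastic line from an under-resolved narrow Lorentzian, which biases
  # the two-stage width estimates; minimizing the pooled profile
  # chi-square over the four dispersion parameters removes that bias
  log_cov <- NULL
  if (!is.null(disp_h) && !is.null(disp_f)) {
    ref <- refine_dispersion(spec, sigma_res, disp_h, disp_f)
    disp_h <- ref$h; disp_f <- ref$f; log_cov <- ref$log_cov
  }
  imm <- if (!is.null(disp_h) && !is.null(disp_f))
    constrained_immobile(spec, sigma_res, disp_h, disp_f)
  else immobile_fraction(tab)
  # fold the dispersion-parameter uncertainty into the immobile-fraction
  # sigma (sensitivity of the pooled estimate to each log parameter)
  if (!is.null(log_cov)) {
    h <- 0.05
    frac_at <- function(dh, th, df2, tf) {
      dh_l <- list(d = dh, tau = th); df_l <- list(d = df2, tau = tf)
      constrained_immobile(spec, sigma_res, dh_l, df_l)$fraction
    }
    p <- c(disp_h$d, max(disp_h$tau, 1e-6), disp_f$d, max(disp_f$tau, 1e-6))
    grad <- vapply(1:4, function(k) {
      pp <- p; pp[k] <- pp[k] * exp(h)
      (frac_at(pp[1], pp[2], pp[3], pp[4]) - imm$fraction) / h
    }, numeric(1))
    v_disp <- drop(t(grad) %*% log_cov %*% grad)
    imm$sigma <- sqrt(imm$sigma^2 + max(v_disp, 0))
  }
  structure(list(records = tab, hydration = disp_h, free = disp_f,
                 immobile = imm, sigma_res = sigma_res),
            class = "qens_fit")
}

#' @export
print.qens_fit <- function(x, ...) {
  cat(sprintf("<qens_fit> %d Q slices (resolution sigma %.3g ueV)\n",
              nrow(x$records), x$sigma_res))
  cat(sprintf("  immobile fraction: %.3f +/- %.3f\n",
              x$immobile$fraction, x$immobile$sigma))
  pr <- function(lbl, d) if (!is.null(d))
    cat(sprintf("  %s water: D = %.3g +/- %.2g A^2/ps, tau = %.3g +/- %.2g ps (%s)\n",
                lbl, d$d, d$d_sigma, d$tau, d$tau_sigma, d$model))
  pr("hydration", x$hydration); pr("free", x$free)
  invisible(x)
}

#' Q-binned, unit-area comparison spectrum
#'
#' Sums a spectrum set over the Q points in the given window and divides
#' by the trapezoidal integral over energy so the curve has unit area —
#' the standard presentation for whole-detector-bank spectral comparisons.
#'
#' @param spec A \code{\link{spectrum_set}}.
#' @param q_lo,q_hi Q window (1/A), closed interval.
#' @return Data frame with \code{omega}, \code{intensity} (1/ueV,
#'   unit area) and \code{sigma}.
#' @export
binned_normalized_spectrum <- function(spec, q_lo, q_hi) {
  sub <- restrict_q(spec, q_lo, q_hi)
  y <- colSums(sub$intensity)
  s <- sqrt(colSums(sub$sigma^2))
  area <- trapz_area(sub$omega, y)
  if (area <= 0) stop("binned spectrum has non-positive area", call. = FALSE)
  data.frame(omega = sub$omega, intensity = y / area, sigma = s / area)
}

trapz_area <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Full width at half maximum of a 1-D spectrum
#'
#' Linear interpolation of the half-maximum crossings on either side of
#' the peak.
#'
#' @param omega Energy grid (ueV), ascending.
#' @param intensity Spectrum values.
#' @return FWHM in ueV.
#' @export
spectrum_fwhm <- function(omega, intensity) {
  ip <- which.max(intensity)
  half <- intensity[ip] / 2
  cross <- function(idx) {
    # idx: indices ordered moving away from the peak
    below <- which(intensity[idx] < half)
    if (!length(below)) return(NA_real_)
    j <- idx[below[1]]; jprev <- idx[max(below[1] - 1, 1)]
    if (j == jprev) return(omega[j])
    stats::approx(intensity[c(jprev, j)], omega[c(jprev, j)], xout = half)$y
  }
  left <- cross(rev(seq_len(ip)))
  right <- cross(ip:length(omega))
  if (is.na(left) || is.na(right))
    stop("spectrum does not fall below half maximum inside the window",
         call. = FALSE)
  right - left
}
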