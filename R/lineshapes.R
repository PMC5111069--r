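# Spectral lineshapes: Lorentzian, Gaussian resolution, their convolution
# (Voigt) through the Faddeeva function, and a direct numerical
# resolution-convolution engine used by the synthetic generator. Keeping
# the generator on the numerical route and the fitter on the closed form
# makes generator/fitter round trips a genuine two-route consistency check.

.faddeeva_cache <- new.env(parent = emptyenv())

# Weideman (1994) rational approximation of the Faddeeva function
# w(z) = exp(-z^2) erfc(-iz), valid for Im(z) >= 0. N = 64 terms gives
# near machine precision over the whole upper half plane.
faddeeva_w <- function(z, N = 64L) {
  key <- as.character(N)
  if (is.null(.faddeeva_cache[[key]])) {
    M <- 2L * N; M2 <- 2L * M
    k <- seq(-M + 1L, M - 1L)
    L <- sqrt(N / sqrt(2))
    t <- L * tan(k * pi / M / 2)
    f <- c(0, exp(-t^2) * (L^2 + t^2))
    f <- f[c((M + 1L):M2, 1L:M)]        # fftshift (even length)
    a <- Re(stats::fft(f)) / M2
    .faddeeva_cache[[key]] <- list(a = rev(a[2:(N + 1L)]), L = L)
  }
  cf <- .faddeeva_cache[[key]]
  iz <- 1i * z
  Z <- (cf$L + iz) / (cf$L - iz)
  p <- rep(0 + 0i, length(z))
  for (ak in cf$a) p <- p * Z + ak
  2 * p / (cf$L - iz)^2 + (1 / sqrt(pi)) / (cf$L - iz)
}

#' Area-normalized spectral lineshapes
#'
#' \code{lorentzian} is the unit-area Lorentzian with half-width at half
#' maximum \code{gamma}; \code{gaussian_lineshape} the unit-area Gaussian
#' of standard deviation \code{sigma} (the instrument resolution shape);
#' \code{voigt_profile} their convolution, evaluated in closed form via
#' the Faddeeva function. All energies in ueV.
#'
#' @param x Energy transfer (ueV), any numeric vector.
#' @param gamma Lorentzian HWHM (ueV), > 0 (0 allowed for
#'   \code{voigt_profile}, giving the pure Gaussian).
#' @param sigma Gaussian standard deviation (ueV), > 0 (0 allowed for
#'   \code{voigt_profile}, giving the pure Lorentzian).
#' @return Spectral density in 1/ueV.
#' @export
lorentzian <- function(x, gamma) {
  stopifnot(gamma > 0)
  gamma / (pi * (x^2 + gamma^2))
}

#' @rdname lorentzian
#' @export
gaussian_lineshape <- function(x, sigma) {
  stopifnot(sigma > 0)
  stats::dnorm(x, sd = sigma)
}

#' @rdname lorentzian
#' @export
voigt_profile <- function(x, sigma, gamma) {
  stopifnot(sigma >= 0, gamma >= 0, sigma + gamma > 0)
  if (sigma == 0) return(lorentzian(x, gamma))
  if (gamma == 0) return(gaussian_lineshape(x, sigma))
  z <- complex(real = x, imaginary = gamma) / (sigma * sqrt(2))
  Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}

#' Jump-diffusion quasi-elastic line width
#'
#' Half-width at half maximum of the diffusive Lorentzian,
#' \eqn{\Gamma(Q) = \hbar D Q^2 / (1 + D Q^2 \tau)}: Fickian
#' (\eqn{\hbar D Q^2}) at low Q, saturating at \eqn{\hbar/\tau} at high Q.
#' \code{tau = 0} gives the simple Fickian law.
#'
#' @param q Momentum transfer (1/A).
#' @param d Diffusion coefficient (A^2/ps).
#' @param tau Residence time (ps), >= 0.
#' @return HWHM in ueV.
#' @export
jump_diffusion_hwhm <- function(q, d, tau = 0) {
  stopifnot(d > 0, tau >= 0)
  dq2 <- d * q^2
  HBAR_UEV_PS * dq2 / (1 + dq2 * tau)
}

# Numerically convolve a unit-area Lorentzian with the Gaussian resolution
# on an arbitrary (uniform) omega grid. The integrand is evaluated on an
# internal grid fine enough to resolve the narrower of the two widths and
# extended past the requested window by the kernel support, so truncation
# and discretization errors stay below ~1e-6 of the peak. The result is
# splined back onto the requested grid (it is smooth on the sigma scale).
convolve_lorentzian_gaussian <- function(omega, gamma, sigma) {
  stopifnot(gamma > 0, sigma > 0)
  domega <- min(diff(omega))
  dx <- min(domega, gamma / 4, sigma / 4)
  half_kernel <- 7 * sigma
  lo <- min(omega) - half_kernel - 2 * dx
  hi <- max(omega) + half_kernel + 2 * dx
  n <- ceiling((hi - lo) / dx) + 1L
  fine <- seq(lo, hi, length.out = n)
  dx <- fine[2] - fine[1]
  lvals <- lorentzian(fine, gamma)
  nk <- ceiling(half_kernel / dx)
  kx <- seq(-nk, nk) * dx
  kern <- stats::dnorm(kx, sd = sigma) * dx
  conv <- stats::convolve(lvals, rev(kern), type = "open")
  # 'open' convolution of length n + 2*nk; aligned so conv[i + nk]
  # corresponds to fine[i]
  vals <- conv[(nk + 1L):(nk + n)]
  stats::spline(fine, vals, xout = omega, method = "natural")$y
}
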