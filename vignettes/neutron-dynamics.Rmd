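---
title: "Methods: elastic-window and quasi-elastic neutron scattering analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic-window and quasi-elastic neutron scattering analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodyn)
```

## The measurement and its models

Incoherent neutron scattering from hydrated biomolecular samples is
dominated by hydrogen, whose atoms are distributed homogeneously enough to
report global average dynamics. `ribodyn` analyses the two complementary
measurements used to characterize thermal dynamics of hydrated ribosomal
subunit samples in high salt:

1. **Elastic fixed-window scans** (backscattering, sub-μeV resolution,
   ~1 ns window). The elastic intensity in the Gaussian approximation is
   $$S_{el}(Q, T) \propto \exp\!\left(-\frac{\langle u^2\rangle(T)\, Q^2}{6}\right),$$
   so the mean square displacement (MSD) $\langle u^2\rangle$ at each
   temperature is $-6\times$ the slope of $\ln S_{el}$ versus $Q^2$. With
   the $/6$ convention $\langle u^2\rangle$ is the full 3-D MSD and equals
   $2 R_g^2$ of the motion. A quasi-harmonic straight-line fit of
   $\langle u^2\rangle$ versus $T$ above the free-water freezing kink
   yields the effective force constant (resilience)
   $$\langle k \rangle = \frac{0.002761}{d\langle u^2\rangle / dT}
   \;\mathrm{N\,m^{-1}},$$
   the numerical constant being $2 k_B$ expressed for MSD in Å² and $T$ in
   K, printed at the precision conventionally used for this quantity.

2. **Quasi-elastic spectra (QENS)** (time-of-flight, tens of μeV
   resolution, ~10 ps window). Each constant-$Q$ spectrum is modelled as
   $$S(Q,\omega) = \Big[a_0\,\delta(\omega) + a_1 L(\Gamma_1) +
   a_2 L(\Gamma_2)\Big] \otimes R(\omega) + b,$$
   with $R$ the Gaussian resolution lineshape, $L$ area-normalized
   Lorentzians for the hydration-water (narrow) and free-water (broad)
   populations, and $b$ a flat background. Widths follow the
   jump-diffusion law
   $\Gamma(Q) = \hbar D Q^2 / (1 + D Q^2 \tau)$ — Fickian at low $Q$,
   saturating at $\hbar/\tau$ — in μeV with $D$ in Å²/ps and $\tau$ in ps.
   The immobile hydrogen fraction is the elastic weight
   $a_0/(a_0+a_1+a_2)$, combined across $Q$ by inverse-variance weighting.

All temperatures are kelvin internally (the 37 °C reference is 310.15 K),
energies μeV, lengths Å, diffusion coefficients Å²/ps.

### The convention constant is shared, not assumed

The Gaussian-approximation constant (6) is a single tagged value
(`gauss_constant()`, overridable via
`options(ribodyn.gauss_constant = )`) read by both the synthetic
generator and the MSD fitter. Changing it rescales extracted MSDs but
leaves generator→fitter round trips exact, and the recovered force
constant is invariant under a *shared* change — a property the test suite
asserts. This isolates a convention that differs between communities from
everything that depends on it.

## Reduction chain

`reduce_chain()` applies, in order: monitor (flux) normalization,
empty-cell subtraction scaled by the sample transmission, and per-$Q$
division by the vanadium reference (a purely elastic incoherent scatterer,
flat in $Q$ up to detector efficiency). Each step is guarded by a
reduction-state flag so it cannot be applied twice, propagates counting
uncertainties (quadrature under subtraction, relative quadrature under
division), and the order matters on non-constant vanadium — asserted by a
two-bin example in the tests. Transmission is a scalar per sample
(default 0.93, consistent with all samples transmitting above 0.9);
multiple-scattering corrections are deliberately out of scope at such
transmissions. The vanadium step realizes the energy-resolution
correction implicitly: models are resolution-convolved before comparison
with data rather than data being deconvolved, which is the numerically
safe direction.

## Synthetic-data generator

The generator exists so that every stage is verifiable by parameter
recovery. `fixture_catalog()` encodes three samples (30S subunit in 3 M
NaCl and 3 M KCl, 50S in 3 M NaCl) whose ground truth comes from the
study's published numbers: water contents 65/62/67 %, immobile fractions
6.3 % (reused for KCl, where none is published) and 9.3 %, MSD at 37 °C of
17.9/16.3/12.1 Å², and above-kink slopes set to $0.002761/\langle k\rangle$
for $\langle k\rangle$ = 0.016/0.018/0.034 N/m. The MSD(T) is
piecewise-linear and continuous with a kink at 273 K; the slope below the
kink is a quarter of the slope above, chosen so the scans flatten below
freezing with an MSD near 10 Å² at the coldest points, matching the
qualitative low-temperature behaviour of such samples. Water populations
contribute no elastic intensity on the ~1 ns window — their quasi-elastic
broadening is far wider than the sub-μeV resolution.

Water dynamics parameters are synthetic, literature-scale stand-ins
(bulk-like free water $D = 0.23$ Å²/ps, $\tau = 1.1$ ps; hydration water
$D = 0.05$ Å²/ps, $\tau = 5$ ps; hydration share of mobile water
0.35/0.30/0.40 across the three fixtures, echoing the reported relative
water-binding trends of Na⁺ vs K⁺ and of the larger subunit). Recovery
tests compare against whatever is configured, never against these
defaults as if they were measured values.

Counting noise is Poisson with `counts_scale` expected counts in a
unit-shape (elastic-peak) bin — $10^5$ throughout the study conditions —
with $\sigma = \sqrt{\max(\text{counts},1)}$ and a private, restorable RNG
stream per dataset. Instrument emulation covers the grids, Gaussian
resolution of the nominal FWHM, a smooth synthetic detector-efficiency
profile (undone by the vanadium step), and a smooth low-amplitude
empty-cell background. It does **not** emulate non-Gaussian resolution
tails, detector geometry and self-shielding, multiple scattering,
$Q$-dependent elastic incoherent structure factors of the internal
dynamics, or Debye–Waller amplitude variation with $Q$ — so passing
recovery tests demonstrate correctness of the estimators under the stated
model, not robustness to every instrumental artifact of real data.

## Numerical choices

**Voigt evaluation.** Lorentzian ⊗ Gaussian profiles are evaluated in
closed form through the Faddeeva function, implemented with Weideman's
rational approximation (N = 64, coefficients cached), accurate to near
machine precision across the upper half-plane; it is validated in the
tests against adaptive quadrature of the defining convolution. (The
textbook route $e^{-z^2}\,\mathrm{erfc}(-iz)$ loses precision
catastrophically for $|\mathrm{Re}\,z| \gtrsim 8$ and is therefore not
used.)

**Generator convolution.** The synthetic generator convolves numerically
instead: Lorentzians are sampled on an internal grid refined to a quarter
of the narrowest width and extended past the energy window by the Gaussian
kernel support, convolved by FFT, and splined back. Edge and
discretization error is below $10^{-6}$ of the peak on all grids used.
Keeping generator (numeric) and fitter (closed-form) on different routes
makes every round-trip test a genuine two-route consistency check.

**Weighted least squares.** Sigmas are first-class: semi-log MSD fits use
$\sigma_{\ln} = \sigma / I$ first-order weights, and parameter covariances
are $(X^T W X)^{-1}$ without residual-variance rescaling when sigmas are
known (nonlinear fits inflate by reduced $\chi^2$ when it exceeds 1).
Normal matrices are inverted after rescaling to unit diagonal with a tiny
ridge fallback, so near-degenerate directions report honestly enormous
variances instead of silently truncated ones. Noiseless data (all sigmas
zero) fall back to unit weights.

**Per-Q QENS fits.** Six parameters ($a_0, a_1, a_2, \Gamma_1, \Gamma_2,
b$) with non-negative amplitudes and widths in (0, window], initialized by
a deterministic five-point grid of width pairs with amplitudes seeded by
linear least squares — reproducible without any RNG. Identifiability
guards flag slices where the fit is ill-posed: widths converging within
10 % of each other (re-fitted as a single Lorentzian), a narrow width
below a tenth of the resolution sigma with non-negligible amplitude
(unresolvable against the elastic line), or a broad width exceeding half
the energy window (indistinguishable from the flat background).

**Dispersion refinement.** The analysis is two-stage — independent per-Q
fits, then jump-diffusion fits of $\Gamma(Q)$ — but the pure two-stage
estimator is biased for the immobile fraction: wherever
$\Gamma_1 \lesssim \sigma_{res}$ the elastic and narrow components are
nearly collinear, per-Q width estimates drift high with understated
uncertainties, and the hydration dispersion can converge to a
self-consistent wrong solution. `fit_qens()` therefore refines the four
dispersion parameters by minimizing the pooled profile chi-square over all
$(Q, \omega)$ points, with per-Q amplitudes profiled out linearly (a
well-conditioned linear solve at every $Q$, unbiased even where a free fit
is degenerate), using a small deterministic multi-start on the hydration
parameters. The reported immobile fraction comes from the
width-constrained linear pass, and its uncertainty includes the
dispersion-parameter covariance via the delta method. Per-Q free-fit
records remain available for diagnostics, and
`immobile_fraction()` still implements the plain two-stage estimator.

**Kink detection.** Continuous two-segment piecewise-linear fits over all
interior breakpoint candidates (≥ 3 points per segment), minimizing
weighted SSE with ties broken toward the lower temperature (so a straight
line deterministically returns the lowest candidate).

**Gaussian-approximation validity.** The classical validity range extends
to about $\langle u^2\rangle Q^2 \approx 4$; with the $/6$ convention the
large-MSD samples studied here exceed that product inside the standard
0.34–0.85 Å⁻¹ window, so the flag is a recorded warning, not an error.
The window itself and the 270 K fit threshold are both configurable;
270 K is kept as the default even though the kink sits near 273 K, so
that fits use the coldest points safely above freezing.

## Problem sizes and test design

The study conditions are: elastic scans over 250–310 K in 5 K steps on a
20-point Q grid (0.19–1.89 Å⁻¹), analysed in the 0.34–0.85 Å⁻¹ window;
QENS at 298 K on 20 Q points (0.21–1.98 Å⁻¹) with 401 energy points over
±1000 μeV; Poisson noise at $10^5$ peak counts. Recovery tests run at
these sizes. Distributional properties use repeated simulation: the
force-constant 2σ-coverage check runs 100 seeds at full size (the elastic
pipeline is cheap); the immobile-fraction unbiasedness check runs 100
seeds on a reduced setting (10 Q points over 0.4–1.98 Å⁻¹, 201 energy
points), a size at which the estimator's behaviour is representative
while each fit stays inexpensive. Area conservation of generated spectra
holds exactly only on an infinite energy window (Lorentzian tails decay
as $\omega^{-2}$); the property test uses slow dynamics on a wide window
where tail leakage is below the tolerance.

## Known limitations

- The Gaussian resolution model is idealized; real backscattering and
  time-of-flight resolutions have non-Gaussian tails
  (`fit_resolution()` can at least fit the width from a measured
  vanadium spectrum).
- Component weights are taken $Q$-independent in the generator; real
  elastic incoherent structure factors decay with $Q$, so the per-Q
  immobile-fraction diagnostics would show structure on real data.
- One Q window is used for all temperatures of a scan; no
  temperature-dependent window selection.
- A fully global fit (amplitudes and widths jointly across $Q$) is not
  offered; the dispersion-level profile refinement above is the closest
  construct and keeps per-Q failures localized.
- Deuteration contrast, multiple scattering and absorption corrections
  are out of scope.
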