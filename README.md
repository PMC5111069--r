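# ribodyn

Thermal molecular dynamics of ribosomal subunits from incoherent neutron
scattering: a tested analysis pipeline for elastic fixed-window
temperature scans and quasi-elastic spectra (QENS) of hydrated
biomolecular samples, built around the case of *Haloarcula marismortui*
30S and 50S ribosomal subunits in 3 M salt.

Crystallography and cryo-EM show *which* conformations a ribosome can
adopt but not the forces or timescales behind them. Neutron scattering
measures both: on the ~1 ns timescale, the temperature dependence of
hydrogen mean square displacements (MSD) gives an effective force
constant ("resilience") for conformational sampling; on the ~10 ps
timescale, quasi-elastic broadening separates free water, hydration
water, and the fraction of hydrogen atoms that appear immobile. The
package is for spectroscopists and modellers who want these quantities
with propagated uncertainties from reduced spectra — and for anyone who
needs a fully synthetic, ground-truth-known testbed for such analyses.

## What it computes

- **MSD extraction** (Gaussian approximation): per temperature,
  `⟨u²⟩ = −6 · d ln S_el / dQ²` by weighted least squares over a chosen
  Q window.
- **Resilience** (quasi-harmonic approximation):
  `⟨k⟩ = 0.002761 / (d⟨u²⟩/dT)` N/m (MSD in Å², T in K) from the
  straight-line fit above the free-water freezing kink, plus the MSD
  evaluated at 37 °C (310.15 K) and a piecewise-linear kink locator.
- **QENS decomposition**: per-Q fits of
  `a₀·R + a₁·L(Γ₁)⊗R + a₂·L(Γ₂)⊗R + b` (Gaussian resolution `R`,
  area-normalized Lorentzians, closed-form Voigt evaluation), jump-
  diffusion dispersion fits `Γ(Q) = ħDQ²/(1+DQ²τ)` for the hydration and
  free water populations, and the immobile hydrogen fraction
  `a₀/(a₀+a₁+a₂)` pooled over Q.
- **Reduction chain**: monitor normalization, transmission-scaled
  empty-cell subtraction, vanadium calibration — flag-guarded, with full
  uncertainty propagation.
- **Synthetic generator**: IN16-style elastic scans and IN5-style QENS
  for three fixture samples whose ground truth encodes the published
  study values, with Poisson counting noise — so every estimator is
  verifiable by parameter recovery.

Spectra travel in NSTSV, a small self-describing tab-separated dialect
(`write_dataset()` / `load_dataset()`); example files live in
`inst/extdata/` (synthetic, generated by the package itself).

## Worked example

Simulate a complete elastic-scan measurement of the 30S fixture, reduce
it, and extract the resilience:

```r
library(ribodyn)

m    <- fixture_catalog()$h30s_nacl          # ground truth: k = 0.016 N/m
raw  <- simulate_experiment(m, instrument_preset("IN16"), "elastic",
                            noise = noise_spec("poisson", 1e5, 42L),
                            temperatures = seq(250, 310, 5),
                            empty_level = 0.05, transmission = 0.93)
red  <- reduce_chain(raw$sample, raw$empty, raw$vanadium,
                     transmission = 0.93)
fc   <- fit_force_constant(fit_msd(red, c(0.34, 0.85)), t_min = 270)
fc
#> <force_constant_result>
#>   <k> = 0.0159 +/- 0.00027 N/m  (slope 0.1737 +/- 0.0029 A^2/K, T > 270 K, n = 8)
#>   MSD(310.15 K) = 17.92 +/- 0.066 A^2
```

(`fit_msd` warns that `⟨u²⟩·Q²` exceeds 4 at these large MSDs — the
Gaussian approximation is being stretched, a known property of these
samples, recorded per temperature in the returned series.)

The recovered force constant (0.0159 ± 0.0003 N/m) and MSD at 37 °C
(17.92 ± 0.07 Å²) agree with the configured truth (0.016 N/m, 17.9 Å²)
within the counting-statistics uncertainty. The same round trip for the
QENS branch (`simulate_experiment(..., "qens")` → `reduce_chain` →
`fit_qens`) recovers the immobile hydrogen fraction and the two water
populations' diffusion parameters.

The `analysis/` directory holds the full workflow as numbered scripts —
`01_simulate.R` through `05_report.R` — which write their tables under
`results/` (e.g. `table1.csv` with the per-sample resilience and MSD,
`immobile_fractions.csv`, and `report.json` with the headline ratios:
the 50S fixture comes out a factor 2.20 ± 0.08 stiffer than the 30S,
whose MSD at 37 °C is 1.47 ± 0.01 times larger).

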