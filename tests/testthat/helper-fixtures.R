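# Shared test fixtures and independent oracles.

# small elastic instrument for fast cases
tiny_in16 <- function(n_q = 8) {
  instrument_config("tiny16", wavelength = 6.27, resolution_fwhm = 0.9,
                    q_min = 0.2, q_max = 1.0, n_q = n_q)
}

# small QENS instrument (same resolution/Q physics as the 5.1 A setting)
small_in5 <- function() {
  instrument_config("IN5_small", wavelength = 5.1, resolution_fwhm = 75,
                    q_min = 0.4, q_max = 1.98, n_q = 10,
                    energy_window = 1000, n_energy = 201)
}

# constant-MSD sample model (flat in T) for exact recovery checks
flat_model <- function(msd = 10, name = "flat") {
  sample_model(name, water_fraction = 0.6, immobile_fraction = 0.1,
               p_hyd = 0.3, p_free = 0.6, msd_ref = msd, slope_above = 0)
}

# hand-built elastic scan: I(Q,T) = amp * exp(-msd(T) Q^2 / 6)
make_scan <- function(q, temps, msd, amp = 1, sigma_rel = 0) {
  I <- amp * exp(-outer(q^2, msd) / 6)
  s <- sigma_rel * I
  elastic_scan(q, temps, I, s,
               metadata = ribodyn:::new_metadata("handmade", "test"))
}

# independent Voigt oracle: adaptive quadrature of the defining convolution
voigt_quadrature <- function(x, sigma, gamma) {
  vapply(x, function(x0)
    stats::integrate(function(u) stats::dnorm(u, 0, sigma) *
                       gamma / (pi * ((x0 - u)^2 + gamma^2)),
                     -Inf, Inf, rel.tol = 1e-11)$value,
    numeric(1))
}

# independent piecewise-linear breakpoint oracle via lm() over all splits
kink_oracle <- function(temps, msd) {
  cand <- temps[vapply(temps, function(tc)
    sum(temps <= tc) >= 3 && sum(temps >= tc) >= 3, logical(1))]
  sse <- vapply(cand, function(tc) {
    fit <- stats::lm(msd ~ I(temps - tc) + I(pmax(temps - tc, 0)))
    sum(stats::residuals(fit)^2)
  }, numeric(1))
  cand[which(sse <= min(sse) + 1e-9 * (1 + min(sse)))][1]
}
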