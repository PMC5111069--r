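test_that("a pure-elastic spectrum fits with vanishing Lorentzian weight", {
  m <- sample_model("frozen", 0.5, 1, 0, 0, msd_ref = 10, slope_above = 0.01)
  instr <- small_in5()
  spec <- simulate_qens(m, instr)
  sig <- fwhm_to_sigma(75)
  rec <- fit_spectrum_q(spec, spec$q[5], sig)
  expect_lt((rec$a1 + rec$a2) / rec$a0, 1e-6)
  # residuals are flat at numerical noise level
  expect_lt(rec$chisq / length(spec$omega), 1e-10)
  # estimator returns exactly 1 in the noiseless case
  qf <- fit_qens(spec, sigma_res = sig)
  expect_equal(qf$immobile$fraction, 1, tolerance = 1e-8)
})

test_that("noiseless two-population widths are recovered to 1e-4 relative", {
  m <- fixture_catalog()$h30s_nacl
  instr <- instrument_preset("IN5_5.1A")
  spec <- simulate_qens(m, instr)
  sig <- fwhm_to_sigma(75)
  q0 <- spec$q[which.min(abs(spec$q - 0.8))]
  rec <- fit_spectrum_q(spec, q0, sig)
  expect_equal(rec$gamma1, jump_diffusion_hwhm(q0, m$d_hyd, m$tau_hyd),
               tolerance = 1e-4)
  expect_equal(rec$gamma2, jump_diffusion_hwhm(q0, m$d_free, m$tau_free),
               tolerance = 1e-4)
  expect_false(rec$single)
  # component weights: a0+a1+a2 plus background area reproduce the
  # spectral area over the window
  area <- ribodyn:::trapz_area(spec$omega, spec$intensity[spec$q == q0, ])
  W <- max(spec$omega)
  model_area <- rec$a0 + rec$a1 * (2 / pi) * atan(W / rec$gamma1) +
    rec$a2 * (2 / pi) * atan(W / rec$gamma2) + rec$b * 2 * W
  expect_equal(model_area / area, 1, tolerance = 0.02)
})

test_that("noiseless end-to-end recovery of all configured QENS parameters", {
  m <- fixture_catalog()$h50s_nacl
  instr <- instrument_preset("IN5_5.1A")
  qf <- fit_qens(simulate_qens(m, instr), instrument = instr)
  expect_equal(qf$immobile$fraction, m$immobile_fraction, tolerance = 1e-3)
  expect_equal(qf$hydration$d, m$d_hyd, tolerance = 1e-3)
  expect_equal(qf$hydration$tau, m$tau_hyd, tolerance = 1e-3)
  expect_equal(qf$free$d, m$d_free, tolerance = 1e-3)
  expect_equal(qf$free$tau, m$tau_free, tolerance = 1e-3)
})

test_that("dispersion fits recover configured laws and the Fickian limit", {
  q <- seq(0.3, 1.9, 0.2)
  g <- jump_diffusion_hwhm(q, 0.23, 1.1)
  gs <- rep(0.5, length(q))
  set.seed(5)
  noisy <- g + stats::rnorm(length(q), 0, 0.5)
  fit <- fit_dispersion(q, noisy, gs)
  expect_lt(abs(fit$d - 0.23), 2 * fit$d_sigma + 1e-6)
  expect_lt(abs(fit$tau - 1.1), 2 * fit$tau_sigma + 1e-6)
  expect_identical(fit$model, "jump")

  fick <- fit_dispersion(q, jump_diffusion_hwhm(q, 0.1, 0), rep(0, length(q)))
  expect_identical(fick$model, "fickian")
  expect_equal(fick$tau, 0)
  expect_equal(fick$d, 0.1, tolerance = 1e-6)

  expect_error(fit_dispersion(q[1:3], g[1:3]), ">= 4")
})

test_that("immobile fraction of a fully mobile sample is near zero", {
  m <- sample_model("mobile", 0.6, 0, 0.4, 0.6, msd_ref = 10,
                    slope_above = 0.01)
  instr <- small_in5()
  spec <- simulate_qens(m, instr, noise = noise_spec("poisson", 1e5, 17L))
  qf <- fit_qens(spec, instrument = instr)
  expect_lt(abs(qf$immobile$fraction), 2 * qf$immobile$sigma + 0.005)
})

test_that("binned spectra are unit-area and track configured dynamics", {
  m30 <- fixture_catalog()$h30s_nacl
  m50 <- fixture_catalog()$h50s_nacl
  instr <- instrument_preset("IN5_5.1A")
  s30 <- simulate_qens(m30, instr)
  s50 <- simulate_qens(m50, instr)
  b30 <- binned_normalized_spectrum(s30, 0.2, 2.0)
  b50 <- binned_normalized_spectrum(s50, 0.2, 2.0)
  expect_equal(ribodyn:::trapz_area(b30$omega, b30$intensity), 1,
               tolerance = 1e-12)
  expect_equal(ribodyn:::trapz_area(b50$omega, b50$intensity), 1,
               tolerance = 1e-12)
  # the small subunit (fewer immobile H) is the broader curve
  expect_gt(spectrum_fwhm(b30$omega, b30$intensity),
            spectrum_fwhm(b50$omega, b50$intensity))

  # single-Q window equals that Q's normalized spectrum
  q1 <- s30$q[4]
  one <- binned_normalized_spectrum(s30, q1 - 1e-6, q1 + 1e-6)
  row <- s30$intensity[4, ]
  expect_equal(one$intensity, row / ribodyn:::trapz_area(s30$omega, row),
               tolerance = 1e-12)
  expect_error(binned_normalized_spectrum(s30, 3, 4), "available Q range")

  # faster configured dynamics broaden the binned curve
  fast <- sample_model("fast", 0.6, 0.1, 0.3, 0.6, d_free = 0.4,
                       msd_ref = 10, slope_above = 0.01)
  slow <- sample_model("slow", 0.6, 0.1, 0.3, 0.6, d_free = 0.1,
                       msd_ref = 10, slope_above = 0.01)
  bf <- binned_normalized_spectrum(simulate_qens(fast, instr), 0.2, 2)
  bs <- binned_normalized_spectrum(simulate_qens(slow, instr), 0.2, 2)
  expect_gt(spectrum_fwhm(bf$omega, bf$intensity),
            spectrum_fwhm(bs$omega, bs$intensity))
})

test_that("immobile-fraction estimates are unbiased over repeated noise", {
  m <- fixture_catalog()$h30s_nacl
  instr <- small_in5()
  fr <- vapply(1:100, function(s) {
    spec <- simulate_qens(m, instr, noise = noise_spec("poisson", 1e5, s))
    fit_qens(spec, instrument = instr)$immobile$fraction
  }, numeric(1))
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - m$immobile_fraction), 2 * se)
})
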