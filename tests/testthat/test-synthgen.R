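test_that("noiseless elastic scans are exactly log-linear in Q^2", {
  m <- fixture_catalog()$h30s_nacl
  in16 <- instrument_preset("IN16")
  temps <- seq(250, 310, 10)
  scan <- simulate_elastic_scan(m, in16, temps)
  msd <- msd_of_T(m, temps)
  for (j in seq_along(temps)) {
    # slope between every pair of Q points, independent of the generator path
    lnI <- log(scan$intensity[, j])
    q2 <- scan$q^2
    slopes <- diff(lnI) / diff(q2)
    expect_equal(slopes, rep(-msd[j] / 6, length(slopes)), tolerance = 1e-12)
  }
})

test_that("a zero-MSD model gives Q-independent elastic intensity", {
  scan <- simulate_elastic_scan(flat_model(0), tiny_in16(),
                                temperatures = c(250, 300))
  expect_equal(max(scan$intensity) - min(scan$intensity), 0)
})

test_that("seeded generation is bit-reproducible and seed-sensitive", {
  m <- fixture_catalog()$h50s_nacl
  n <- noise_spec("poisson", 1e5, 7L)
  a <- simulate_elastic_scan(m, tiny_in16(), noise = n)
  b <- simulate_elastic_scan(m, tiny_in16(), noise = n)
  expect_identical(a$intensity, b$intensity)
  c2 <- simulate_elastic_scan(m, tiny_in16(),
                              noise = noise_spec("poisson", 1e5, 8L))
  expect_false(identical(a$intensity, c2$intensity))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_elastic_scan(m, tiny_in16(), noise = n))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("vanadium is flat in Q and Poisson noise scales as 1/sqrt(counts)", {
  big <- instrument_config("vbig", 6.27, 0.9, 0.1, 1.9, 1000)
  van0 <- simulate_vanadium(big)
  expect_equal(max(van0$intensity), min(van0$intensity))
  van <- simulate_vanadium(big, noise_spec("poisson", 1e5, 13L))
  rel <- stats::sd(van$intensity) / mean(van$intensity)
  expect_equal(rel, 1 / sqrt(1e5), tolerance = 0.1)
  expect_equal(mean(van$sigma / van$intensity), 1 / sqrt(1e5),
               tolerance = 0.05)
})

test_that("empty-cell level zero means zero background", {
  empty <- simulate_empty_cell(tiny_in16(), 0, kind = "elastic",
                               temperatures = c(250, 300))
  expect_true(all(empty$intensity == 0))
})

test_that("a fully immobile sample reproduces the resolution lineshape", {
  m <- sample_model("frozen", 0.5, 1, 0, 0, msd_ref = 10, slope_above = 0.01)
  instr <- small_in5()
  spec <- simulate_qens(m, instr)
  ref <- gaussian_lineshape(spec$omega, fwhm_to_sigma(75))
  for (i in seq_along(spec$q)) {
    ratio <- spec$intensity[i, ] / ref
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  }
})

test_that("jump-diffusion width is Fickian at low Q and saturates at high Q", {
  d <- 0.23; tau <- 1.1
  q_small <- c(1e-4, 1e-3)
  expect_equal(jump_diffusion_hwhm(q_small, d, tau) / q_small^2,
               rep(658.2119569 * d, 2), tolerance = 1e-5)
  expect_equal(jump_diffusion_hwhm(500, d, tau), 658.2119569 / tau,
               tolerance = 1e-4)
  expect_true(all(diff(jump_diffusion_hwhm(seq(0.1, 3, 0.1), d, tau)) > 0))
})

test_that("numeric resolution convolution matches the closed-form Voigt", {
  instr <- instrument_preset("IN5_5.1A")
  om <- omega_grid(instr)
  sig <- fwhm_to_sigma(instr$resolution_fwhm)
  m <- fixture_catalog()$h30s_nacl
  for (g in c(jump_diffusion_hwhm(1.2, m$d_hyd, m$tau_hyd),
              jump_diffusion_hwhm(1.2, m$d_free, m$tau_free), 1.45, 298)) {
    num <- ribodyn:::convolve_lorentzian_gaussian(om, g, sig)
    cf <- voigt_profile(om, sig, g)
    expect_lt(max(abs(num - cf)) / max(cf), 1e-6)
  }
})

test_that("closed-form Voigt agrees with adaptive quadrature", {
  xs <- c(0, 5, 40, 200, 900)
  for (g in c(1.45, 65, 298)) {
    expect_equal(voigt_profile(xs, 31.85, g), voigt_quadrature(xs, 31.85, g),
                 tolerance = 1e-8)
  }
  # degenerate limits
  expect_equal(voigt_profile(xs, 31.85, 0), gaussian_lineshape(xs, 31.85))
  expect_equal(voigt_profile(xs, 0, 65), lorentzian(xs, 65))
})

test_that("QENS spectra are nonnegative with Q-independent integrated area", {
  spec0 <- simulate_qens(fixture_catalog()$h30s_nacl, small_in5())
  expect_true(all(spec0$intensity >= 0))

  # area conservation is a property of the infinite-window lineshapes;
  # testing it on a grid needs slow dynamics and a wide energy window so
  # Lorentzian tail leakage stays below the tolerance
  m <- sample_model("slow", 0.6, 0.2, 0.4, 0.4, d_free = 0.01, tau_free = 5,
                    d_hyd = 0.005, tau_hyd = 10, msd_ref = 10,
                    slope_above = 0.01)
  wide <- instrument_config("wide", 5.1, 75, 0.4, 1.98, 5,
                            energy_window = 2e4, n_energy = 2001)
  spec <- simulate_qens(m, wide)
  areas <- apply(spec$intensity, 1, function(y)
    ribodyn:::trapz_area(spec$omega, y))
  expect_lt(diff(range(areas)) / mean(areas), 1e-3)
})

test_that("a narrow energy window records a truncation warning", {
  m <- sample_model("fast", 0.6, 0.1, 0.3, 0.6, d_free = 0.5,
                    msd_ref = 10, slope_above = 0.01)
  spec <- simulate_qens(m, instrument_preset("IN5_10A"))
  expect_match(spec$metadata$warnings, "truncation")
  ok <- simulate_qens(fixture_catalog()$h30s_nacl,
                      instrument_preset("IN5_5.1A"))
  expect_null(ok$metadata$warnings)
})
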