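test_that("noiseless scans return the configured MSD at every temperature", {
  temps <- seq(250, 310, 10)
  scan <- simulate_elastic_scan(flat_model(10), tiny_in16(), temps)
  series <- suppressWarnings(fit_msd(scan, c(0.2, 1.0)))
  expect_equal(series$msd, rep(10, length(temps)), tolerance = 1e-10)
  expect_equal(rg_squared(series), rep(5, length(temps)))

  flat <- fit_msd(simulate_elastic_scan(flat_model(0), tiny_in16(), temps),
                  c(0.2, 1.0))
  expect_lt(max(abs(flat$msd)), 1e-10)
  expect_true(all(flat$gauss_valid))
})

test_that("fit_msd enforces window size and drops bad points with warning", {
  temps <- c(260, 280)
  scan <- make_scan(c(0.3, 0.5, 0.7, 0.9), temps, c(5, 6))
  expect_error(fit_msd(scan, c(0.45, 0.55)), ">= 3 Q points")
  scan$intensity[2:3, 1] <- -1
  expect_error(suppressWarnings(fit_msd(scan, c(0.25, 0.95))),
               "T = 260")
  scan2 <- make_scan(c(0.3, 0.5, 0.7, 0.9), temps, c(5, 6))
  scan2$intensity[2, 2] <- 0
  expect_warning(fit_msd(scan2, c(0.25, 0.95)), "dropped")
})

test_that("quasi-harmonic conversion matches the hand-checked arithmetic", {
  temps <- seq(272, 312, 5)
  mk_series <- function(slope, intercept = 1) {
    scan <- make_scan(seq(0.3, 0.9, 0.2), temps, intercept + slope * temps)
    fit_force_constant(suppressWarnings(fit_msd(scan, c(0.25, 0.95))), 270)
  }
  fc <- mk_series(0.1726)
  expect_equal(fc$k_eff, 0.002761 / 0.1726, tolerance = 1e-10)
  expect_equal(fc$k_eff, 0.016, tolerance = 1e-3)
  expect_equal(mk_series(0.002761)$k_eff, 1, tolerance = 1e-10)
  # reference-temperature evaluation lies on the fitted line
  expect_equal(fc$msd_at_ref, 1 + 0.1726 * 310.15, tolerance = 1e-8)
  expect_equal(fc$n_points_fit, length(temps[temps > 270]))

  down <- mk_series(-0.05, intercept = 30)
  expect_false(down$physical)
  expect_true(is.na(down$k_eff))

  short <- suppressWarnings(fit_msd(make_scan(seq(0.3, 0.9, 0.2),
                                              c(250, 260, 280),
                                              c(10, 10, 10)),
                                    c(0.25, 0.95)))
  expect_error(fit_force_constant(short, 270), ">= 3 temperatures")
})

test_that("noisy fixture recovery is consistent with the reference values", {
  m <- fixture_catalog()$h30s_nacl
  raw <- simulate_experiment(m, instrument_preset("IN16"), "elastic",
                             noise = noise_spec("poisson", 1e5, 42L))
  red <- reduce_chain(raw$sample, raw$empty, raw$vanadium)
  series <- suppressWarnings(fit_msd(red, c(0.34, 0.85)))
  fc <- fit_force_constant(series, 270)
  expect_lt(abs(fc$msd_at_ref - 17.9),
            2 * sqrt(fc$msd_at_ref_sigma^2 + 0.9^2))
  expect_lt(abs(fc$k_eff - 0.016), 2 * sqrt(fc$k_sigma^2 + 0.001^2))
})

test_that("kink detection matches the exhaustive-breakpoint oracle", {
  m <- fixture_catalog()$h30s_nacl
  temps <- seq(250, 310, 2.5)
  scan <- simulate_elastic_scan(m, instrument_preset("IN16"), temps)
  series <- suppressWarnings(fit_msd(scan, c(0.34, 0.85)))
  kink <- detect_kink(series)
  expect_equal(as.numeric(kink), 272.5)  # nearest grid T below 273
  expect_equal(as.numeric(kink), kink_oracle(series$temperature, series$msd))

  # straight line: SSE flat, tie broken toward the lowest-T candidate
  line <- make_scan(seq(0.3, 0.9, 0.2), temps, 1 + 0.1 * temps)
  ls <- suppressWarnings(fit_msd(line, c(0.25, 0.95)))
  expect_equal(as.numeric(detect_kink(ls)), temps[3])

  # noisy fixture: breakpoint within 5 K of the configured 273 K
  raw <- simulate_experiment(m, instrument_preset("IN16"), "elastic",
                             temperatures = temps,
                             noise = noise_spec("poisson", 1e5, 42L))
  red <- reduce_chain(raw$sample, raw$empty, raw$vanadium)
  noisy <- suppressWarnings(fit_msd(red, c(0.34, 0.85)))
  expect_lt(abs(as.numeric(detect_kink(noisy)) - 273), 5)

  expect_error(detect_kink(ls[1:4, ]), ">= 6")
})

test_that("recovered force-constant errors cover the truth across seeds", {
  m <- fixture_catalog()$h30s_nacl
  in16 <- instrument_preset("IN16")
  hits <- 0
  for (s in 1:100) {
    raw <- simulate_experiment(m, in16, "elastic",
                               noise = noise_spec("poisson", 1e5, s))
    red <- reduce_chain(raw$sample, raw$empty, raw$vanadium)
    fc <- fit_force_constant(suppressWarnings(fit_msd(red, c(0.34, 0.85))),
                             270)
    if (abs(fc$k_eff - 0.016) <= 2 * fc$k_sigma) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("stiffer configured dynamics give smaller recovered k", {
  in16 <- instrument_preset("IN16")
  ks <- vapply(c(0.08, 0.12, 0.17), function(sl) {
    m <- sample_model("var", 0.6, 0.1, 0.3, 0.6, msd_ref = 18,
                      slope_above = sl)
    scan <- simulate_elastic_scan(m, in16)
    fit_force_constant(suppressWarnings(fit_msd(scan, c(0.34, 0.85))),
                       270)$k_eff
  }, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("recovered k is invariant under a shared convention change", {
  m <- fixture_catalog()$h50s_nacl
  in16 <- instrument_preset("IN16")
  run <- function() {
    scan <- simulate_elastic_scan(m, in16)
    fit_force_constant(suppressWarnings(fit_msd(scan, c(0.34, 0.85))),
                       270)$k_eff
  }
  k6 <- run()
  k3 <- withr::with_options(list(ribodyn.gauss_constant = 3), run())
  expect_equal(k3, k6, tolerance = 1e-10)
  expect_equal(k6, 0.034, tolerance = 1e-8)
})
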