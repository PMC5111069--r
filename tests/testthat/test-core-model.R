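test_that("NSTSV round trip preserves every field to text precision", {
  tmp <- withr::local_tempfile(fileext = ".nstsv")
  in16 <- tiny_in16()
  scan <- simulate_elastic_scan(flat_model(), in16,
                                temperatures = c(250, 270, 290),
                                noise = noise_spec("poisson", 1e5, 3L))
  write_dataset(scan, tmp)
  back <- load_dataset(tmp, "elastic")
  for (f in c("q", "temperatures", "intensity", "sigma", "monitor"))
    expect_equal(back[[f]], scan[[f]], tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$metadata$sample, scan$metadata$sample)

  qspec <- simulate_qens(fixture_catalog()$h30s_nacl,
                         instrument_config("q4", 5.1, 75, 0.3, 0.9, 3,
                                           energy_window = 300, n_energy = 21),
                         noise = noise_spec("poisson", 1e4, 4L))
  write_dataset(qspec, tmp)
  qback <- load_dataset(tmp)
  expect_s3_class(qback, "spectrum_set")
  expect_equal(qback$intensity, qspec$intensity, tolerance = 1e-12)
  expect_equal(qback$omega, qspec$omega, tolerance = 1e-12)
  expect_equal(qback$temperature, qspec$temperature)

  van <- simulate_vanadium(in16, noise_spec("poisson", 1e5, 5L))
  write_dataset(van, tmp)
  vback <- load_dataset(tmp, "vanadium")
  expect_equal(vback$intensity, van$intensity, tolerance = 1e-12)
})

test_that("writing is deterministic and load-write is a fixed point", {
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  t3 <- withr::local_tempfile()
  scan <- simulate_elastic_scan(flat_model(), tiny_in16(),
                                temperatures = c(250, 280, 310),
                                noise = noise_spec("poisson", 1e5, 9L))
  write_dataset(scan, t1)
  write_dataset(scan, t2)
  expect_identical(readBin(t1, "raw", 1e6), readBin(t2, "raw", 1e6))
  write_dataset(load_dataset(t1), t3)
  expect_identical(readBin(t1, "raw", 1e6), readBin(t3, "raw", 1e6))
})

test_that("elastic long format has |T| x |Q| data rows", {
  tmp <- withr::local_tempfile()
  scan <- make_scan(c(0.3, 0.5, 0.7, 0.9), c(260, 280, 300), rep(5, 3))
  write_dataset(scan, tmp)
  lines <- readLines(tmp)
  data_rows <- lines[!startsWith(lines, "#")][-1]
  expect_length(data_rows, 12L)
})

test_that("malformed inputs are rejected with informative errors", {
  tmp <- withr::local_tempfile()
  scan <- make_scan(c(0.3, 0.5, 0.7), c(260, 280), rep(5, 2))
  write_dataset(scan, tmp)
  lines <- readLines(tmp)

  # header line without a tab-separated value
  writeLines(c(lines[1], "# broken-header-line", lines[-1]), tmp)
  expect_error(load_dataset(tmp), "line 2")

  # temperatures out of order
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  swap <- body
  swap[2:3] <- body[3:2]  # exchange the two T rows of the first Q block
  writeLines(c(hdr, swap), tmp)
  expect_error(load_dataset(tmp), "out of order")

  # negative sigma
  bad <- sub("(\t[0-9.e+-]+)$", "\t-1", body[2])
  writeLines(c(hdr, body[1], bad, body[-(1:2)]), tmp)
  expect_error(load_dataset(tmp), "sigma")

  # missing required key
  writeLines(c(hdr[!grepl("monitor", hdr)], body), tmp)
  expect_error(load_dataset(tmp), "monitor")
})

test_that("validation rejects shape/grid inconsistencies", {
  expect_error(elastic_scan(c(0.3, 0.5), c(260, 280),
                            matrix(1, 3, 2), matrix(0, 3, 2)),
               "dimensions disagree")
  expect_error(elastic_scan(c(0.5, 0.3), c(260, 280),
                            matrix(1, 2, 2), matrix(0, 2, 2)),
               "strictly increasing")
  expect_error(spectrum_set(c(0.3, 0.5), c(-10, 0, 5), matrix(1, 2, 3),
                            matrix(0, 2, 3), temperature = 298),
               "symmetric")
  expect_error(vanadium_ref(c(0.3, 0.5), c(1, 0), c(0.1, 0.1)),
               "positive")
})

test_that("restrict_q keeps exactly the closed-interval points", {
  scan <- make_scan(c(0.2, 0.5, 1.0), c(260, 280, 300), rep(5, 3))
  one <- restrict_q(scan, 0.4, 0.6)
  expect_equal(one$q, 0.5)
  expect_equal(one$metadata$q_window, c(0.4, 0.6))

  # full range is the identity on the data
  full <- restrict_q(scan, 0.1, 2)
  expect_equal(full$q, scan$q)
  expect_equal(full$intensity, scan$intensity)

  # endpoints are included
  ends <- restrict_q(scan, 0.2, 1.0)
  expect_equal(ends$q, c(0.2, 0.5, 1.0))

  expect_error(restrict_q(scan, 1.2, 1.4), "available Q range")

  in16 <- instrument_preset("IN16")
  sub <- restrict_q(simulate_elastic_scan(flat_model(), in16,
                                          temperatures = 300),
                    0.34, 0.85)
  expect_true(all(sub$q >= 0.34 & sub$q <= 0.85))
})

test_that("restrict_q commutes with write/load", {
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  scan <- simulate_elastic_scan(flat_model(), tiny_in16(),
                                temperatures = c(250, 280, 310),
                                noise = noise_spec("poisson", 1e5, 11L))
  write_dataset(restrict_q(scan, 0.3, 0.8), t1)
  write_dataset(scan, t2)
  a <- load_dataset(t1)
  b <- restrict_q(load_dataset(t2), 0.3, 0.8)
  expect_equal(a$q, b$q, tolerance = 1e-12)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
})

test_that("shipped elastic fixture matches its generating configuration", {
  path <- system.file("extdata", "h30s_nacl_elastic.nstsv",
                      package = "ribodyn")
  scan <- load_dataset(path, "elastic")
  expect_length(scan$q, 20L)
  expect_true(all(scan$q >= 0.19 & scan$q <= 1.89))
  expect_identical(scan$metadata$sample, "h30s_nacl")
})
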