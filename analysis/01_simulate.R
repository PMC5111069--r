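#!/usr/bin/env Rscript
# Stage 1: generate the raw synthetic datasets for the three ribosomal
# fixture samples — elastic fixed-window scans (backscattering setting,
# 250-310 K) for all three, QENS at 298 K (5.1 A time-of-flight setting)
# for the two NaCl samples — together with the matching empty-cell and
# vanadium runs. Poisson counting noise at 1e5 peak counts; fixed seeds
# so every later stage is reproducible.

suppressMessages(library(ribodyn))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

catalog <- fixture_catalog()
in16 <- instrument_preset("IN16")
in5 <- instrument_preset("IN5_5.1A")

elastic_seeds <- c(h30s_nacl = 42L, h30s_kcl = 43L, h50s_nacl = 44L)
for (nm in names(elastic_seeds)) {
  raw <- simulate_experiment(catalog[[nm]], in16, "elastic",
                             noise = noise_spec("poisson", 1e5,
                                                elastic_seeds[[nm]]),
                             temperatures = seq(250, 310, 5),
                             empty_level = 0.05, transmission = 0.93)
  write_dataset(raw$sample, file.path(out_dir, paste0(nm, "_elastic.nstsv")))
  write_dataset(raw$empty, file.path(out_dir, paste0(nm, "_elastic_empty.nstsv")))
  write_dataset(raw$vanadium, file.path(out_dir, paste0(nm, "_elastic_vanadium.nstsv")))
  message("wrote elastic set for ", nm)
}

qens_seeds <- c(h30s_nacl = 7L, h50s_nacl = 8L)
for (nm in names(qens_seeds)) {
  raw <- simulate_experiment(catalog[[nm]], in5, "qens",
                             noise = noise_spec("poisson", 1e5,
                                                qens_seeds[[nm]]),
                             temperature = 298,
                             empty_level = 0.05, transmission = 0.93)
  write_dataset(raw$sample, file.path(out_dir, paste0(nm, "_qens.nstsv")))
  write_dataset(raw$empty, file.path(out_dir, paste0(nm, "_qens_empty.nstsv")))
  write_dataset(raw$vanadium, file.path(out_dir, paste0(nm, "_qens_vanadium.nstsv")))
  message("wrote QENS set for ", nm)
}
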