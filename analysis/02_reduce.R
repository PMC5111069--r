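#!/usr/bin/env Rscript
# Stage 2: run the correction chain on every raw dataset from stage 1 —
# monitor (flux) normalization, transmission-scaled empty-cell
# subtraction, vanadium calibration — and write the reduced spectra.

suppressMessages(library(ribodyn))

in_dir <- "results/data"
out_dir <- "results/reduced"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sets <- c("h30s_nacl_elastic", "h30s_kcl_elastic", "h50s_nacl_elastic",
          "h30s_nacl_qens", "h50s_nacl_qens")
for (s in sets) {
  sample <- load_dataset(file.path(in_dir, paste0(s, ".nstsv")))
  empty <- load_dataset(file.path(in_dir, paste0(s, "_empty.nstsv")))
  van <- load_dataset(file.path(in_dir, paste0(s, "_vanadium.nstsv")),
                      "vanadium")
  red <- reduce_chain(sample, empty, van, transmission = 0.93)
  write_dataset(red, file.path(out_dir, paste0(s, "_reduced.nstsv")))
  message(s, ": ", paste(red$metadata$reduction_state, collapse = " -> "))
}
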