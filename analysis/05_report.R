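#!/usr/bin/env Rscript
# Stage 5: assemble the summary report and the headline between-sample
# comparisons: how much softer (smaller force constant) and more mobile
# (larger MSD at 37 C) the small subunit is than the large one.

suppressMessages(library(ribodyn))

tab <- read.csv("results/table1.csv")
imm <- read.csv("results/immobile_fractions.csv")

stiff <- compare_samples(tab, tab, "h50s_nacl", "h30s_nacl")
soft <- compare_samples(tab, tab, "h30s_nacl", "h50s_nacl")

message(sprintf("k(50S) / k(30S)   = %.2f +/- %.2f  (rounds to %d)",
                stiff$k_ratio, stiff$k_ratio_sigma, stiff$k_ratio_rounded))
message(sprintf("MSD(30S)/MSD(50S) = %.2f +/- %.2f  (rounds to %.1f)",
                soft$msd_ratio, soft$msd_ratio_sigma,
                soft$msd_ratio_one_decimal))

doc <- list(
  resilience = tab,
  immobile_fractions = imm,
  comparisons = list(
    k_ratio_50S_over_30S = stiff$k_ratio,
    k_ratio_sigma = stiff$k_ratio_sigma,
    k_ratio_rounded = stiff$k_ratio_rounded,
    msd_ratio_30S_over_50S = soft$msd_ratio,
    msd_ratio_sigma = soft$msd_ratio_sigma,
    msd_ratio_one_decimal = soft$msd_ratio_one_decimal),
  meta = list(q_window = c(0.34, 0.85), t_min = 270,
              counts_scale = 1e5,
              package_version = as.character(packageVersion("ribodyn"))))
jsonlite::write_json(doc, "results/report.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows", pretty = TRUE)
message("wrote results/report.json")
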