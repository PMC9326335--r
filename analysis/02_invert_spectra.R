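#!/usr/bin/env Rscript
# Stage 2: calibrate each raw spectrum against the dark and 5%-standard
# reference, reject artifact spectra, average retained replicates per
# tumor-visit, invert the reflectance model for (tHb, StO2, a, b), derive
# HbO2/HbO, and compute per-tumor fold changes against week 1.

source("analysis/00_config.R")

run_pipeline(study_config, study_dir, stages = "optics")

perf <- read.csv(file.path(study_dir, "perfusion.csv"))
truth <- read.csv(file.path(study_dir, "truth_perfusion.csv"))
ok <- !perf$rejected & !is.na(perf$StO2)
m <- merge(perf[ok, ], truth, by = c("tumor_id", "week"))
message(sprintf(
  "inverted %d/%d tumor-visits; median |StO2 error| %.4f, median tHb rel. error %.2f%%",
  sum(ok), nrow(perf),
  median(abs(m$StO2 - m$sto2_true)),
  100 * median(abs(m$tHb - m$thb_true) / m$thb_true)))
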