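# Shared configuration for the analysis workflow. Each numbered script
# sources this file so every stage sees the same cohort and seed and the
# results accumulate in one directory.

library(drstrend)

study_dir <- "results/study"

study_config <- cohort_config(
  n_per_group = c(CG = 14L, MET = 20L, MTD = 27L),  # study arm sizes
  weeks = 1:6,
  seed = 1234L,
  missing_rate = 0.05,
  artifact_rate = 0.05,
  spectra_per_visit = 3L
)

study_genes <- c("Vegf", "Hif1a", "Gapdh")
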