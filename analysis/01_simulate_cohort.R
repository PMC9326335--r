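#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-arm cohort with known ground
# truth — raw reflectance spectra (plus dark and 5%-standard reference),
# triplicate qPCR Ct tables with standard curves, weekly tumor scores and
# vessel-label masks. Everything downstream is validated against the
# ground-truth files written here.

source("analysis/00_config.R")

run_pipeline(study_config, study_dir, stages = "simulate",
             genes = study_genes)

truth <- read.csv(file.path(study_dir, "truth_spectra.csv"))
message(sprintf("simulated %d raw spectra for %d tumors (%.1f%% corrupted)",
                nrow(truth), length(unique(truth$tumor_id)),
                100 * mean(truth$corrupted)))
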