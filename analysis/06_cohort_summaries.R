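#!/usr/bin/env Rscript
# Stage 6: cohort bookkeeping — weekly tumor-score proportions (missing
# visits excluded from denominators), per-tumor score trajectories, and
# microvessel density from the vessel-label masks with a Kruskal-Wallis
# comparison across arms.

source("analysis/00_config.R")

run_pipeline(study_config, study_dir, stages = "cohort")

mvd <- jsonlite::read_json(file.path(study_dir, "mvd_test.json"))
message(sprintf(
  "MVD medians: CG=%.2f%% MET=%.2f%% MTD=%.2f%%; Kruskal-Wallis H=%.1f, p=%.3g",
  mvd$medians$CG, mvd$medians$MET, mvd$medians$MTD,
  mvd$statistic, mvd$p_value))
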