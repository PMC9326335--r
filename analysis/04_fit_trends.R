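#!/usr/bin/env Rscript
# Stage 4: fit the penalized-spline trend model (one smooth per arm plus
# arm intercepts, REML-selected smoothing) to each perfusion fold-change
# metric and each gene's relative expression; write fitted curves with
# pointwise intervals.

source("analysis/00_config.R")

run_pipeline(study_config, study_dir, stages = "fit")

summ <- jsonlite::read_json(file.path(study_dir, "fit_summaries.json"))
for (m in names(summ)) {
  message(sprintf("%-6s smooth EDF: %s", m,
                  paste(sprintf("%s=%.2f", names(summ[[m]]$edf),
                                unlist(summ[[m]]$edf)), collapse = " ")))
}
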