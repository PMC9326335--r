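#!/usr/bin/env Rscript
# Stage 5: pairwise differences between fitted arm trends with 95%
# simultaneous confidence bands (posterior simulation, 10,000 draws) and
# extraction of the week intervals where each band excludes zero.

source("analysis/00_config.R")

run_pipeline(study_config, study_dir, stages = "compare")

win <- jsonlite::read_json(file.path(study_dir, "windows.json"),
                           simplifyVector = TRUE)
if (length(win) == 0 || nrow(as.data.frame(win)) == 0) {
  message("no significant windows detected")
} else {
  win <- as.data.frame(win)
  for (i in seq_len(nrow(win))) {
    message(sprintf("%-6s %-8s %s difference, weeks %.1f-%.1f",
                    win$metric[i], win$pair[i], win$direction[i],
                    win$start[i], win$end[i]))
  }
}
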