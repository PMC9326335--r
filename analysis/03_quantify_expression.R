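#!/usr/bin/env Rscript
# Stage 3: RNA-quality filter (260/280 in [1.8, 2.0]), triplicate
# aggregation, per-gene efficiency estimation from the standard curves,
# and efficiency-corrected (Pfaffl) relative expression normalized to the
# control arm at week 1, with Gapdh as the reference gene.

source("analysis/00_config.R")

run_pipeline(study_config, study_dir, stages = "qpcr")

expr <- read.csv(file.path(study_dir, "expression.csv"))
effs <- jsonlite::read_json(file.path(study_dir, "efficiencies.json"))
message("estimated efficiencies: ",
        paste(sprintf("%s=%.3f", names(effs), unlist(effs)),
              collapse = ", "))
mtd1 <- expr[expr$group == "MTD" & expr$week == 1 & expr$gene == "Vegf", ]
message(sprintf("MTD week-1 Vegf mean relative expression: %.3f (n=%d)",
                mean(mtd1$relative_expression), nrow(mtd1)))
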