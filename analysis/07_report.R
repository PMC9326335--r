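#!/usr/bin/env Rscript
# Stage 7: render the summary figures — fitted trend panels per metric,
# pairwise difference bands with significant windows, weekly score
# proportions, and the MVD violin plot.

source("analysis/00_config.R")

figs <- make_report(study_dir)
message("wrote ", length(figs), " figures under ",
        file.path(study_dir, "figures"))
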