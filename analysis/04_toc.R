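#!/usr/bin/env Rscript
# Trial Opportunities Compass on the demo bundle: classify the 20 most
# common conditions into the 3x3 participant x trial grid per sponsor class.

source("analysis/00_config.R")

cfg <- demo_config()
res <- run_pipeline(cfg, stages = "toc")

tab <- res$state$toc$table
cat("region occupancy (conditions x sponsor classes):\n")
print(sort(table(tab$region), decreasing = TRUE))
inv <- tab[tab$region == "Many participants / Few trials", ]
if (nrow(inv) > 0) {
  cat("\npotential investment opportunities (many participants, few trials):\n")
  print(inv[, c("condition", "sponsor_class", "participant_count", "trial_count")],
        row.names = FALSE)
}
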