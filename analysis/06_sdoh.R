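#!/usr/bin/env Rscript
# Adjusted social-determinants analysis on the demo bundle, plus the
# stratified means and cohort summary report.

source("analysis/00_config.R")

cfg <- demo_config()
res <- run_pipeline(cfg, stages = c("sdoh", "report"))

sd <- res$state$sdoh
cat(sprintf("%d coefficients tested across %d outcomes; Bonferroni threshold %0.2e\n",
            sd$m, length(sd$n_included), sd$threshold))
sig <- sd$results[sd$results$significant, ]
cat(sprintf("%d significant covariate levels\n", nrow(sig)))
if (nrow(sig) > 0) {
  print(utils::head(sig[order(sig$p),
                        c("outcome", "covariate", "level", "ratio",
                          "ci_low", "ci_high")], 10), row.names = FALSE)
}

strata <- res$state$report$strata
metro <- strata[strata$stratifier == "metro", ]
cat("\nmean matched trials by location:\n")
print(metro[, c("level", "n", "mean", "ci_low", "ci_high")], row.names = FALSE)
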