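#!/usr/bin/env Rscript
# Match every demo participant against the filtered registry on condition,
# age, sex at birth, and zip3; write per-participant matched-trial counts.

source("analysis/00_config.R")

cfg <- demo_config()
res <- run_pipeline(cfg, stages = "match")

m <- res$state$match
counts <- m$counts$total_matches
cat(sprintf("%d of %d trials pass the recruiting/interventional/adult/US filter\n",
            length(m$filtered), length(read_registry(cfg$registry)$records)))
geo <- read_geo_lookup(cfg$geo)
prof <- trial_metro_profile(m$filtered, geo)
cat(sprintf("%0.0f%% of filtered trials have a metropolitan site; %0.0f%% a nonmetropolitan one\n",
            100 * prof$metro_fraction, 100 * prof$nonmetro_fraction))
ci <- stats::qnorm(0.975) * stats::sd(counts) / sqrt(length(counts))
cat(sprintf("mean matched trials per participant: %0.1f [95%% CI, %0.1f-%0.1f]; %0.1f%% match none\n",
            mean(counts), mean(counts) - ci, mean(counts) + ci,
            100 * mean(counts == 0)))
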