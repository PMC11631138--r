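# Shared configuration for the numbered analysis scripts. Everything runs on
# the seeded demo bundle: a 2,000-participant synthetic cohort and a
# 1,000-trial synthetic registry snapshot dated 2023-02-14, with lookups and
# the fixture phecode map.

library(trialopps)

demo_config <- function() {
  run_config(outdir = "results/demo",
             seed = 42L,
             n_participants = 2000L,
             n_trials = 1000L,
             reference_date = as.Date("2023-02-14"))
}
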