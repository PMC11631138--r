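Package: trialopps
Title: Matching EHR-Phenotyped Cohorts to Clinical-Trial Registries and
    Characterizing the Trial-Opportunity Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing clinical-trial opportunities for an
    EHR-phenotyped cohort. Participants are phenotyped from ICD event streams
    with phecode grouping under a rule-of-two presence rule, then matched to
    an offline snapshot of trial-registry records on condition, age, sex at
    birth, and 3-digit zip code geography. The per-participant matched-trial
    counts feed three analyses: the Trial Opportunities Compass, a 3x3
    percentile grid of participant counts against trial counts per sponsor
    class; a phenome-wide scan of matched-trial counts with negative-binomial
    regression and Bonferroni control; and an adjusted analysis of social
    determinants of health. Seeded generators emulate both data sources so
    the full pipeline is testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
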