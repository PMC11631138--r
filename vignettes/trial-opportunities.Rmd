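---
title: "Characterizing trial opportunities for an EHR-phenotyped cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing trial opportunities for an EHR-phenotyped cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialopps)
```

## The problem

Large national health cohorts hold EHR, demographic, and survey data for
hundreds of thousands of participants, and trial registries describe tens of
thousands of recruiting studies. Pairing the two answers a planning
question: *which conditions, places, and populations have trial
opportunities, and where are the gaps?* `trialopps` implements a broad
participant-trial matching pipeline and three analyses on top of the
per-participant matched-trial count: a portfolio grid (the Trial
Opportunities Compass), a phenome-wide scan, and an adjusted
social-determinants analysis.

Access-restricted cohort data and ephemeral registry snapshots cannot ship
with a package, so every stage is specified against documented file formats
and exercised end to end on seeded synthetic data with planted, known truth.

## Phenotyping: from ICD events to conditions

A participant's raw EHR signal is a stream of dated ICD-9-CM/ICD-10-CM
codes. Codes are grouped into phecodes — physician-curated condition
groupings — by exact (code, vocabulary) lookup in a mapping table, and a
condition counts as *present* only with at least `min_instances = 2`
qualifying instances (the "rule of two", which suppresses rule-out and
one-off miscoded diagnoses).

"Instance" is not self-defining. We count **distinct event dates per
phecode**, aggregating across all ICD codes that map to the phecode: two
codes recorded at the same encounter are one instance. This is the stricter
of the common conventions; `distinct_dates = FALSE` switches to raw row
counting for sensitivity analyses. No parent/child phecode rollup is
applied: a mapped phecode stands alone, since rollup would require the full
hierarchy table, and the matching step treats each condition independently
anyway. Unmapped codes are tallied into a coverage ratio, never an error —
real maps are incomplete.

Phecode domains are consolidated to seven analysis domains: the six with
the most trial activity (Mental, Cancer, Neurological, Endocrine/Metabolic,
Circulatory, Respiratory) plus `Other` for everything else (digestive,
hematopoietic, sense organs, symptoms, musculoskeletal, genitourinary,
injuries & poisoning, pregnancy complications, dermatologic, congenital
anomalies, infectious diseases).

## The registry snapshot and its filter

Trials arrive as offline JSONL snapshots mirroring the public registry API
vocabulary (`inst/extdata/registry_schema.md`). The analysis set retains
trials that are `Recruiting`, `Interventional`, have a stated minimum age
of at least 18 years (the boundary is inclusive), and list at least one US
site. Two judgment calls:

* **Site-level status.** When a site carries its own status, only
  `Recruiting` sites count toward the US-site and geography rules; a site
  without a status counts. The snapshot-level filter concerns active
  recruitment, and discarding sites with explicit non-recruiting statuses
  is the conservative reading.
* **Unknown vocabulary values** (new statuses, study types) are preserved
  verbatim and treated as non-matching, so future snapshots degrade safely
  rather than erroring.

Age fields use registry grammar (`"18 Years"`, `"6 Months"`, `"N/A"`) and
convert with fixed divisors (months/12, weeks/52, days/365.25). A missing
maximum age means no upper bound.

## Matching

A trial matches a participant when all four rules hold:

1. **Condition** — at least one phecode linked to the trial's condition
   terms is present in the participant's profile. Linkage is exact
   normalized-string equality (lowercase, punctuation stripped, whitespace
   collapsed) against phecode descriptions plus an explicit synonym table.
   No fuzzy or substring matching: every link is auditable, and the synonym
   table is the extension point.
2. **Age** — participant age at the reference date lies in the trial's
   window. Age is reference year minus birth year; the reference date
   defaults to the registry snapshot date, since a matching analysis is a
   cross-section at that date.
3. **Sex at birth** — `All` admits anyone; `Male`/`Female` admit the same
   sex at birth; intersex or unknown participants match only `All`, because
   the registry vocabulary has no finer value.
4. **Geography** — the participant's zip3 equals the zip3 of at least one
   eligible US site. Zip3 equality, not distance: that is the resolution
   at which cohort geography is released.

A trial matched through several phecodes counts once toward the total and
once toward each distinct consolidated domain among its linking phecodes,
so per-domain counts can overlap but each is bounded by the total.

## The Trial Opportunities Compass

For the `top_k` most common conditions, the TOC crosses participant counts
with per-sponsor-class trial counts and labels each cell with one of nine
regions, `{Few, Some, Many} x {Few, Some, Many}`, using percentile cutoffs
(default 20th/80th). Thresholds interpolate linearly between order
statistics; values *strictly below* the low threshold are `Few`, *strictly
above* the high one `Many`, and ties fall inward to `Some` — the strict
inequalities leave the boundary to the implementer, and inward ties keep
the extreme labels meaningful. Participant-axis thresholds are computed
once across conditions; trial-axis thresholds per sponsor class, matching
the per-sponsor panels such a compass is read in. TOC trial counts use
condition linkage only; restricting to trials actually matched to a
participant is available behind `restrict_to_matched`.

## Count regressions

Matched-trial counts are overdispersed, so both analyses use NB2
negative-binomial regression (variance $\mu + \alpha\mu^2$) with a log
link, dispersion estimated jointly by maximum likelihood (convergence
tolerance $10^{-8}$, 100-iteration cap). Constant or equidispersed data sit
at the Poisson boundary of the family and are refit there with
$\alpha = 0$; collinear terms are dropped with a warning; non-convergence
yields a flagged, excluded fit rather than an exception. Summaries are
count ratios $e^{\beta}$ with Wald 95% intervals and two-sided Wald
p-values — ratio-style intervals are what such analyses report, and a
likelihood-ratio option was judged not worth the extra fits at
phenome-wide scale. P-values below the double-precision floor are reported
as the bound $10^{-300}$ with an underflow flag; the exact magnitude is
carried as $-\log_{10} p$ for plotting, capped at 300 in the Manhattan
export.

The **phenome-wide scan** fits one regression per phecode: the count
outcome against the presence indicator, adjusting for age (continuous
years), sex at birth, metro location, race/ethnicity, education, low
income, disability, and the number of present conditions. Missing
covariates exclude a participant listwise for that analysis, with the
included n logged. Phecodes with fewer than `min_cases = 20` cases are
skipped: far below that, the NB fit is numerically fragile and the Wald
interval meaningless. Significance is Bonferroni at 0.05 over the number
of phecodes actually tested.

The **SDoH analysis** fits one multivariable regression per outcome (total
count and each domain count) on demographics, socioenvironmental factors
(metro location, low income, education, English proficiency, food
insecurity, discrimination and social-support scores, housing quality,
neighborhood cohesion), and condition count. Categorical reference levels
are fixed: White, Female, Metropolitan, Good housing, not low income, no
food insecurity, education 11 or below, not English proficient. Reference
rows appear with ratio 1 and no interval. Bonferroni control is applied
across all non-reference coefficients over all outcomes — a conservative
choice; per-outcome control would be defensible too.

Derived covariates worth noting: the metro flag is a zip3 lookup emulating
the USDA rural-urban classification; the low-income flag compares annual
household income against the (zip3, household size, fiscal year) limit,
*inclusive* at the boundary ("did not exceed"); the under-50/50-plus split
is descriptive only — regressions use continuous age.

## What the generators emulate — and what they do not

`simulate_cohort()` draws demographics from the emulated study's published
margins (92.5% metropolitan, 63.8% female, 52.2% White, 35% under 50,
35.2% low income, 30.2% with a disability), condition presence from a
log-uniform prevalence spread over the fixture phecodes (no published
per-condition prevalence table exists to copy), at-least-two-distinct-date
event streams for present conditions, single-date noise events that the
rule-of-two must remove, and a configurable rate of unmapped ICD codes.
`simulate_registry()` emits qualifying trials by construction — with a
contamination rate injecting completed/observational/underage/non-US
records for filter testing — and plants a 0.95 trial-level probability of
at least one metropolitan site. One global seed fans out to fixed
per-generator substreams, so any stage can be regenerated independently.

The generators emulate *marginals and mechanisms*, not joint structure:
covariates are drawn independently, condition co-occurrence is random, and
trial condition portfolios are uniform over the vocabulary. Passing tests
therefore demonstrate that the pipeline computes the declared quantities
correctly, not that it reproduces any real population's numbers — the
published population-level results require access-restricted cohort data
and a registry snapshot that no longer exists.

Two generators carry exact planted truth. `simulate_nb_counts()` draws from
the NB2 model itself. `simulate_planted_linkage()` builds an end-to-end
ground truth: a vocabulary of unit conditions, each linked to exactly one
all-permissive trial with sites in every cohort zip3, plus a planted marker
phecode linked to none. Carriers of the marker carry twice the expected
number of unit conditions, so the true count ratio for marker presence is
exactly 2 and the matched count must equal the number of unit conditions
carried — any phenotyping, linkage, or matching defect breaks the identity.
Validation scans on this construction adjust for age and sex only: the
planted mechanism operates *through* condition burden, so adjusting for the
condition count would absorb the effect by design rather than reveal a bug.

## Problem sizes and numerical checks

The test suite validates matching against an exhaustive brute-force oracle
on fifty 50x100 cohort-registry instances, the rule-of-two against a
group-by oracle on a ~36,000-event stream, interval coverage for a planted
ratio of 1.5 over 100 replicates at n = 5,000, phenome-wide type-I error
over 200 null phecodes x 15 replicates at n = 1,000 (3,000 p-values,
binomial tolerance ±0.01 around 0.05), and the end-to-end planted twofold
enrichment over 50 seeds at n = 400. The demo bundle used by the
`analysis/` scripts is 2,000 participants x 1,000 trials. These sizes make
the Monte-Carlo tolerances tight enough to be informative while keeping a
full run in minutes; all are parameters, not constants.

## Known limitations

* Matching is deliberately *broad*: free-text eligibility criteria, labs,
  and genotypes are out of scope, so matched counts measure opportunity,
  not eligibility in the granular sense — and availability is not
  accessibility.
* Condition linkage by exact normalized string misses synonymous trial
  terms unless the synonym table supplies them.
* Phecode phenotyping inherits EHR ascertainment bias; the rule-of-two
  trades sensitivity for specificity.
* The SDoH and PheWAS models are associational; no causal reading is
  intended.
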