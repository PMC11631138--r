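# Seeded generators emulating the two data sources (EHR-phenotyped cohort,
# trial-registry snapshot) plus direct negative-binomial count simulation
# with known truth. One global seed fans out to fixed per-generator
# substreams so each generator can be re-run independently.

substream_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * offset) %% .Machine$integer.max
}

#' Default zip3 pool for the simulators
#'
#' Forty synthetic zip3 areas, 30 metropolitan and 10 nonmetropolitan.
#'
#' @return data.frame with `zip3`, `metro_flag`.
#' @export
default_geo_lookup <- function() {
  data.frame(zip3 = sprintf("%03d", 1:40),
             metro_flag = rep(c("Metropolitan", "Nonmetropolitan"), c(30, 10)),
             stringsAsFactors = FALSE)
}

#' Default income-limits lookup for the simulators
#'
#' One limit per (zip3, household size 1-8, fiscal year): a base of 30 000
#' plus 5 000 per additional household member, scaled slightly by area.
#'
#' @param geo Zip3 pool (default [default_geo_lookup()]).
#' @param fiscal_year Fiscal year (default 2023).
#' @return data.table keyed like [read_income_limits()] output.
#' @export
default_income_limits <- function(geo = default_geo_lookup(), fiscal_year = 2023L) {
  grid <- data.table::CJ(zip3 = geo$zip3, household_size = 1:8,
                         fiscal_year = as.integer(fiscal_year))
  metro <- stats::setNames(geo$metro_flag, geo$zip3)[grid$zip3] == "Metropolitan"
  grid[, income_limit := (30000 + 5000 * (household_size - 1)) * ifelse(metro, 1.1, 0.9)]
  data.table::setkey(grid, zip3, household_size, fiscal_year)
  grid[]
}

#' Cohort simulation parameters
#'
#' Default marginal probabilities follow the published cohort tabulation of
#' the emulated study population: 35% under 50, 63.8% female, 52.2%
#' self-reported White, 92.5% metropolitan, 35.2% low income, 30.2% with a
#' disability, and so on. Condition prevalences default to a log-uniform
#' spread over the phecodes of the supplied map.
#'
#' @param n Number of participants.
#' @param map A `phecode_map` (conditions to simulate).
#' @param seed Integer seed.
#' @param geo Zip3 pool.
#' @param limits Income-limits lookup.
#' @param p_metro,p_age_under50,p_low_income,p_disability Marginal
#'   probabilities.
#' @param p_sex,p_race,p_education Named probability vectors (must sum to 1).
#' @param prevalence Optional named vector phecode -> prevalence; default
#'   log-uniform on \[0.01, 0.4\].
#' @param mean_instances Mean qualifying instances per present condition
#'   (at least 2; default 3).
#' @param noise_rate Probability that an absent condition emits exactly one
#'   single-date event (filtered out by the rule-of-two; default 0.05).
#' @param unmapped_rate Expected number of events per participant with ICD
#'   codes absent from the map (default 0.5).
#' @param missing_education,missing_disability,missing_income,missing_sdoh
#'   Missingness rates.
#' @param fiscal_year Fiscal year for income limits.
#' @param reference_year Year used to convert ages to birth years.
#' @return List of validated parameters (class `cohort_sim_params`).
#' @export
cohort_sim_params <- function(n = 500L, map, seed = 1L,
                              geo = default_geo_lookup(),
                              limits = default_income_limits(geo),
                              p_metro = 0.925,
                              p_age_under50 = 0.35,
                              p_low_income = 0.352,
                              p_disability = 0.302,
                              p_sex = c(Male = 0.3618, Female = 0.638, Intersex = 0.0002),
                              p_race = c(White = 0.522, Black = 0.198,
                                         Hispanic = 0.191, Asian = 0.0241,
                                         MENA = 0.0052, NHOPI = 0.0011,
                                         Multiple = 0.015, Remaining = 0.0436),
                              p_education = c(`11orBelow` = 0.101, `12orGED` = 0.482,
                                              CollegeGrad = 0.219, AdvancedDegree = 0.198),
                              prevalence = NULL,
                              mean_instances = 3,
                              noise_rate = 0.05,
                              unmapped_rate = 0.5,
                              missing_education = 0.03,
                              missing_disability = 0.2,
                              missing_income = 0.2,
                              missing_sdoh = 0.1,
                              fiscal_year = 2023L,
                              reference_year = 2023L) {
  probs <- c(p_metro, p_age_under50, p_low_income, p_disability,
             p_sex, p_race, p_education, noise_rate,
             missing_education, missing_disability, missing_income, missing_sdoh)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (v in list(p_sex, p_race, p_education)) {
    if (abs(sum(v) - 1) > 1e-6) {
      stop("categorical probabilities must sum to 1", call. = FALSE)
    }
  }
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (mean_instances < 2) stop("mean_instances must be at least 2", call. = FALSE)
  rm(probs, v)
  structure(as.list(environment()), class = "cohort_sim_params")
}

#' Simulate an EHR-phenotyped cohort
#'
#' Deterministic given the seed. Each present condition emits at least two
#' events on distinct dates (so it passes the rule-of-two); noise conditions
#' emit exactly one event and are filtered out by the rule; a configurable
#' rate of events carries ICD codes absent from the map.
#'
#' @param params A `cohort_sim_params`.
#' @param dir Optional directory; when given, writes `cohort.csv`,
#'   `icd_events.csv`, `zip3_metro.csv`, `income_limits.csv`.
#' @return List with `cohort` (data.table), `events` (data.table), `geo`,
#'   `limits`, and `params`.
#' @export
simulate_cohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  set.seed(substream_seed(p$seed, 1L))
  n <- as.integer(p$n)
  geo <- p$geo
  metro_zips <- geo$zip3[geo$metro_flag == "Metropolitan"]
  nonmetro_zips <- geo$zip3[geo$metro_flag == "Nonmetropolitan"]

  cohort <- data.table::data.table(
    participant_id = if (n > 0) sprintf("P%06d", seq_len(n)) else character())
  if (n > 0) {
    under50 <- runif(n) < p$p_age_under50
    age <- ifelse(under50, sample(18:49, n, replace = TRUE),
                  sample(50:89, n, replace = TRUE))
    cohort[, birth_year := p$reference_year - age]
    cohort[, sex_at_birth := sample(names(p$p_sex), n, replace = TRUE, prob = p$p_sex)]
    cohort[, race_ethnicity := sample(names(p$p_race), n, replace = TRUE, prob = p$p_race)]
    is_metro <- runif(n) < p$p_metro
    cohort[, zip3 := ifelse(is_metro,
                            sample(metro_zips, n, replace = TRUE),
                            sample(nonmetro_zips, n, replace = TRUE))]
    cohort[, education := sample(names(p$p_education), n, replace = TRUE, prob = p$p_education)]
    cohort[, household_size := sample(1:6, n, replace = TRUE)]
    # draw the low-income flag first, then an income consistent with it
    low <- runif(n) < p$p_low_income
    key <- data.table::data.table(zip3 = cohort$zip3,
                                  household_size = cohort$household_size,
                                  fiscal_year = as.integer(p$fiscal_year))
    lim <- p$limits[key, on = c("zip3", "household_size", "fiscal_year")]$income_limit
    cohort[, annual_income := round(ifelse(low, lim * runif(n, 0.3, 1.0),
                                           lim * runif(n, 1.05, 3.0)))]
    cohort[, disability := ifelse(runif(n) < p$p_disability, "Yes", "No")]
    cohort[, english_proficient := ifelse(runif(n) < 0.9, "Yes", "No")]
    cohort[, food_insecurity := ifelse(runif(n) < 0.15, "Yes", "No")]
    cohort[, discrimination_score := round(pmin(pmax(rnorm(n, 2, 0.8), 1), 5), 2)]
    cohort[, social_support_score := round(pmin(pmax(rnorm(n, 3.5, 0.8), 1), 5), 2)]
    cohort[, housing_quality := ifelse(runif(n) < 0.85, "Good", "Substandard")]
    cohort[, neighborhood_cohesion_score := round(pmin(pmax(rnorm(n, 3, 0.6), 1), 4), 2)]
    # missingness
    cohort[runif(n) < p$missing_education, education := NA_character_]
    cohort[runif(n) < p$missing_disability, disability := NA_character_]
    miss_inc <- runif(n) < p$missing_income
    cohort[miss_inc, `:=`(annual_income = NA_real_, household_size = NA_integer_)]
    for (col in c("english_proficient", "food_insecurity", "housing_quality")) {
      cohort[runif(n) < p$missing_sdoh, (col) := NA_character_]
    }
    for (col in c("discrimination_score", "social_support_score",
                  "neighborhood_cohesion_score")) {
      cohort[runif(n) < p$missing_sdoh, (col) := NA_real_]
    }
  } else {
    cohort[, `:=`(birth_year = integer(), sex_at_birth = character(),
                  race_ethnicity = character(), zip3 = character(),
                  education = character(), household_size = integer(),
                  annual_income = numeric(), disability = character(),
                  english_proficient = character(), food_insecurity = character(),
                  discrimination_score = numeric(), social_support_score = numeric(),
                  housing_quality = character(), neighborhood_cohesion_score = numeric())]
  }

  # condition prevalences: log-uniform spread over the map's phecodes
  phecodes <- names(p$map$phecodes)
  prev <- p$prevalence %||% stats::setNames(
    10^runif(length(phecodes), log10(0.01), log10(0.4)), phecodes)
  map_rows <- split(seq_len(nrow(p$map$table)), p$map$table$phecode)
  date_pool <- seq(as.Date("2015-01-01"), as.Date("2022-06-30"), by = "day")

  ev_list <- list()
  for (i in seq_len(n)) {
    pid <- cohort$participant_id[i]
    u <- runif(length(phecodes))
    present <- phecodes[u < prev[phecodes]]
    noise <- setdiff(phecodes[u < prev[phecodes] + p$noise_rate], present)
    for (ph in present) {
      k <- 2L + rpois(1L, p$mean_instances - 2)
      rows <- map_rows[[ph]]
      picks <- rows[sample.int(length(rows), k, replace = TRUE)]
      ev_list[[length(ev_list) + 1L]] <- data.table::data.table(
        participant_id = pid,
        code = p$map$table$icd_code[picks],
        vocabulary = p$map$table$vocabulary[picks],
        date = sample(date_pool, k, replace = FALSE))
    }
    if (length(noise) > 0L) {
      rows <- vapply(map_rows[noise], function(r) r[sample.int(length(r), 1L)], 1L)
      ev_list[[length(ev_list) + 1L]] <- data.table::data.table(
        participant_id = pid,
        code = p$map$table$icd_code[rows],
        vocabulary = p$map$table$vocabulary[rows],
        date = sample(date_pool, length(noise), replace = TRUE))
    }
    k_un <- rpois(1L, p$unmapped_rate)
    if (k_un > 0L) {
      ev_list[[length(ev_list) + 1L]] <- data.table::data.table(
        participant_id = pid,
        code = sprintf("ZZ%02d.%d", sample.int(99, k_un, replace = TRUE),
                       sample.int(9, k_un, replace = TRUE)),
        vocabulary = "ICD10CM",
        date = sample(date_pool, k_un, replace = TRUE))
    }
  }
  events <- if (length(ev_list)) data.table::rbindlist(ev_list) else
    data.table::data.table(participant_id = character(), code = character(),
                           vocabulary = character(), date = as.Date(character()))

  out <- list(cohort = cohort[], events = events[], geo = geo,
              limits = p$limits, params = p)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(cohort, file.path(dir, "cohort.csv"))
    data.table::fwrite(events, file.path(dir, "icd_events.csv"))
    data.table::fwrite(geo, file.path(dir, "zip3_metro.csv"))
    data.table::fwrite(p$limits, file.path(dir, "income_limits.csv"))
  }
  out
}

#' Registry simulation parameters
#'
#' By default every generated trial passes the recruiting / interventional /
#' adult / US-site filter; a contamination rate injects non-qualifying
#' records (completed, observational, underage minimum, non-US) for filter
#' testing. The metro-site probability defaults to 0.95, matching the share
#' of recruiting trials with at least one metropolitan site in the emulated
#' registry snapshot.
#'
#' @param n Number of trials.
#' @param map A `phecode_map` (condition-term vocabulary from descriptions).
#' @param seed Integer seed.
#' @param geo Zip3 pool.
#' @param p_sponsor Named probabilities over raw sponsor classes.
#' @param p_sex Named probabilities over sex eligibility.
#' @param p_metro_site Probability that a trial has at least one
#'   metropolitan site (additional sites are metropolitan with the same
#'   probability).
#' @param max_sites Sites per trial are uniform on 1..`max_sites`.
#' @param p_no_max_age Probability the trial has no maximum age.
#' @param unmatched_term_rate Probability a condition term is junk (links to
#'   no phecode).
#' @param contamination Probability a trial is made non-qualifying.
#' @return List of validated parameters (class `registry_sim_params`).
#' @export
registry_sim_params <- function(n = 300L, map, seed = 1L,
                                geo = default_geo_lookup(),
                                p_sponsor = c(NIH = 0.08, INDUSTRY = 0.30,
                                              OTHER = 0.55, FED = 0.04,
                                              OTHER_GOV = 0.03),
                                p_sex = c(All = 0.8, Female = 0.12, Male = 0.08),
                                p_metro_site = 0.95,
                                max_sites = 5L,
                                p_no_max_age = 0.5,
                                unmatched_term_rate = 0.1,
                                contamination = 0) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  probs <- c(p_sponsor, p_sex, p_metro_site, p_no_max_age,
             unmatched_term_rate, contamination)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  for (v in list(p_sponsor, p_sex)) {
    if (abs(sum(v) - 1) > 1e-6) stop("categorical probabilities must sum to 1", call. = FALSE)
  }
  rm(probs, v)
  structure(as.list(environment()), class = "registry_sim_params")
}

#' Simulate a trial-registry snapshot
#'
#' @param params A `registry_sim_params`.
#' @param path Optional JSONL output path.
#' @return List of trial records (write with [write_registry()]).
#' @export
simulate_registry <- function(params, path = NULL) {
  stopifnot(inherits(params, "registry_sim_params"))
  p <- params
  set.seed(substream_seed(p$seed, 2L))
  geo <- p$geo
  metro_zips <- geo$zip3[geo$metro_flag == "Metropolitan"]
  nonmetro_zips <- geo$zip3[geo$metro_flag == "Nonmetropolitan"]
  vocab <- unname(p$map$phecodes)
  sponsor_map <- default_sponsor_map()

  records <- vector("list", p$n)
  for (i in seq_len(p$n)) {
    n_terms <- sample.int(3L, 1L)
    terms <- sample(vocab, n_terms, replace = FALSE)
    junk <- runif(n_terms) < p$unmatched_term_rate
    terms[junk] <- sprintf("zz unlinked condition %d", sample.int(999L, sum(junk)))
    min_age <- sample(c(18, 18, 18, 21, 40, 50, 65), 1L)
    max_age <- if (runif(1) < p$p_no_max_age) NA_real_ else sample(66:100, 1L)
    n_sites <- sample.int(p$max_sites, 1L)
    # p_metro_site is a trial-level property: the probability that a trial
    # has at least one metropolitan site
    has_metro <- runif(1) < p$p_metro_site
    site_metro <- if (has_metro) {
      c(TRUE, runif(n_sites - 1L) < p$p_metro_site)
    } else {
      rep(FALSE, n_sites)
    }
    zips <- ifelse(site_metro, sample(metro_zips, n_sites, replace = TRUE),
                   sample(nonmetro_zips, n_sites, replace = TRUE))
    sites <- data.frame(zip3 = zips,
                        country = "United States",
                        site_status = ifelse(runif(n_sites) < 0.8, "Recruiting",
                                             NA_character_),
                        stringsAsFactors = FALSE)
    status <- "Recruiting"
    type <- "Interventional"
    if (runif(1) < p$contamination) {
      defect <- sample(c("completed", "observational", "underage", "non_us"), 1L)
      if (defect == "completed") status <- "Completed"
      if (defect == "observational") type <- "Observational"
      if (defect == "underage") min_age <- 12
      if (defect == "non_us") sites$country <- "Canada"
    }
    raw_class <- sample(names(p$p_sponsor), 1L, prob = p$p_sponsor)
    records[[i]] <- new_trial_record(
      trial_id = sprintf("NCT%08d", i),
      overall_status = status,
      study_type = type,
      min_age_years = min_age,
      max_age_years = max_age,
      sex_eligibility = sample(names(p$p_sex), 1L, prob = p$p_sex),
      condition_terms = terms,
      sites = sites,
      sponsor_class = sponsor_map[[raw_class]])
  }
  if (!is.null(path)) write_registry(records, path)
  records
}

#' Simulate counts from the NB2 model with known truth
#'
#' @param n Number of observations.
#' @param intercept Intercept on the log scale.
#' @param coef Named numeric vector of true coefficients (log scale), one
#'   per covariate.
#' @param covariate_spec Named list describing each covariate:
#'   `list(type = "binary", p = 0.5)` or `list(type = "normal", mean, sd)`.
#'   Defaults to binary with p = 0.5 for every coefficient.
#' @param dispersion NB2 dispersion alpha (0 gives Poisson draws).
#' @param seed Integer seed.
#' @return List with `design` (data.frame), `counts`, and `truth`.
#' @export
simulate_nb_counts <- function(n, intercept, coef = numeric(),
                               covariate_spec = NULL, dispersion = 1,
                               seed = 1L) {
  if (dispersion < 0) stop("dispersion must be non-negative", call. = FALSE)
  set.seed(substream_seed(seed, 3L))
  design <- as.data.frame(stats::setNames(
    lapply(names(coef), function(nm) {
      sp <- covariate_spec[[nm]] %||% list(type = "binary", p = 0.5)
      switch(sp$type,
             binary = rbinom(n, 1L, sp$p %||% 0.5),
             normal = rnorm(n, sp$mean %||% 0, sp$sd %||% 1),
             stop("unknown covariate type: ", sp$type, call. = FALSE))
    }), names(coef)))
  eta <- rep(intercept, n)
  for (nm in names(coef)) eta <- eta + coef[[nm]] * design[[nm]]
  mu <- exp(eta)
  counts <- if (dispersion == 0) rpois(n, mu) else
    rnbinom(n, size = 1 / dispersion, mu = mu)
  list(design = design, counts = counts,
       truth = list(intercept = intercept, coef = coef, dispersion = dispersion))
}

#' Simulate an end-to-end cohort/registry pair with a planted enrichment
#'
#' Builds a synthetic phecode vocabulary of "unit" conditions, each linked to
#' exactly one permissive trial (all sexes, minimum age 18, no maximum, an
#' eligible US site in every cohort zip3), plus one planted marker phecode
#' linked to no trial. Every participant carries a Poisson number of unit
#' conditions; carriers of the planted phecode carry `effect` times as many
#' in expectation, so the true count ratio for planted-phecode presence is
#' exactly `effect` and the matched-trial count equals the number of unit
#' conditions carried. Used to validate the whole pipeline (phenotyping,
#' matching, regression) against a known truth.
#'
#' @param n Number of participants.
#' @param lambda Mean number of unit conditions for non-carriers.
#' @param n_unit_phecodes Size of the unit-condition vocabulary.
#' @param effect True count ratio for carriers (default 2).
#' @param carrier_prob Probability of carrying the planted phecode.
#' @param seed Integer seed.
#' @return List with `cohort`, `events`, `map`, `registry`, `geo`, `limits`,
#'   and `truth` (`planted_phecode`, `ratio`).
#' @export
simulate_planted_linkage <- function(n = 400L, lambda = 8, n_unit_phecodes = 40L,
                                     effect = 2, carrier_prob = 0.5, seed = 1L) {
  set.seed(substream_seed(seed, 4L))
  raw_domains <- c("mental disorders", "neoplasms", "neurological",
                   "endocrine/metabolic", "circulatory system", "respiratory",
                   "digestive")
  unit_ph <- sprintf("U%03d", seq_len(n_unit_phecodes))
  map_df <- data.frame(
    icd_code = c(sprintf("ZU%03d", seq_len(n_unit_phecodes)), "ZPL.0"),
    vocabulary = "ICD10CM",
    phecode = c(unit_ph, "PL.1"),
    description = c(sprintf("unit condition %03d", seq_len(n_unit_phecodes)),
                    "planted marker condition"),
    domain = c(rep_len(raw_domains, n_unit_phecodes), "symptoms"),
    stringsAsFactors = FALSE)
  map <- as_phecode_map(map_df)
  geo <- utils::head(default_geo_lookup(), 10)
  limits <- default_income_limits(geo)

  cohort <- data.table::data.table(
    participant_id = sprintf("P%06d", seq_len(n)),
    birth_year = 2023L - sample(20:80, n, replace = TRUE),
    sex_at_birth = sample(c("Male", "Female"), n, replace = TRUE),
    race_ethnicity = "White",
    zip3 = sample(geo$zip3, n, replace = TRUE),
    education = "12orGED",
    household_size = 2L,
    annual_income = 50000,
    disability = "No",
    english_proficient = "Yes", food_insecurity = "No",
    discrimination_score = 2, social_support_score = 3.5,
    housing_quality = "Good", neighborhood_cohesion_score = 3)

  carrier <- runif(n) < carrier_prob
  date_pool <- seq(as.Date("2018-01-01"), as.Date("2022-06-30"), by = "day")
  ev_list <- list()
  for (i in seq_len(n)) {
    k <- rpois(1L, lambda * if (carrier[i]) effect else 1)
    k <- min(k, n_unit_phecodes)
    mine <- c(if (k > 0) sample(unit_ph, k), if (carrier[i]) "PL.1")
    if (length(mine) == 0L) next
    codes <- map_df$icd_code[match(mine, map_df$phecode)]
    dates <- sample(date_pool, 2L * length(mine), replace = FALSE)
    ev_list[[i]] <- data.table::data.table(
      participant_id = cohort$participant_id[i],
      code = rep(codes, each = 2L),
      vocabulary = "ICD10CM",
      date = dates)
  }
  events <- data.table::rbindlist(ev_list)

  all_sites <- data.frame(zip3 = geo$zip3, country = "United States",
                          site_status = "Recruiting", stringsAsFactors = FALSE)
  registry <- lapply(seq_len(n_unit_phecodes), function(j) {
    new_trial_record(trial_id = sprintf("NCT%08d", j),
                     overall_status = "Recruiting",
                     study_type = "Interventional",
                     min_age_years = 18, max_age_years = NA_real_,
                     sex_eligibility = "All",
                     condition_terms = sprintf("unit condition %03d", j),
                     sites = all_sites,
                     sponsor_class = "Academic/Other")
  })
  list(cohort = cohort[], events = events[], map = map, registry = registry,
       geo = geo, limits = limits,
       truth = list(planted_phecode = "PL.1", ratio = effect))
}
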