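test_that("condition terms link by normalized exact match plus synonyms", {
  map <- tiny_map()
  linkage <- build_condition_linkage(map, synonyms = c(T2DM = "250.2"))
  expect_equal(link_conditions(make_trial(condition_terms = "Type 2 Diabetes!"),
                               linkage), "250.2")
  expect_equal(link_conditions(make_trial(condition_terms = "t2dm"), linkage),
               "250.2")
  expect_equal(link_conditions(make_trial(condition_terms = "unknown thing"),
                               linkage), character(0))
  # no substring matching
  expect_equal(link_conditions(make_trial(condition_terms = "type 2 diabetes mellitus"),
                               linkage), character(0))
})

test_that("all four eligibility rules gate a match", {
  map <- tiny_map()
  linkage <- build_condition_linkage(map)
  trial <- make_trial(min_age_years = 18, max_age_years = 65,
                      sex_eligibility = "All", zips = "372",
                      condition_terms = "type 2 diabetes")
  ok <- trial_matches_participant(trial, 53, "Female", "372", "250.2", linkage)
  expect_true(ok$match)
  expect_equal(ok$linking_phecodes, "250.2")
  # (a) condition
  expect_false(trial_matches_participant(trial, 53, "Female", "372", "300.1",
                                         linkage)$match)
  # (b) age below minimum, above maximum, and missing max = unbounded
  expect_false(trial_matches_participant(trial, 17, "Female", "372", "250.2",
                                         linkage)$match)
  expect_false(trial_matches_participant(trial, 70, "Female", "372", "250.2",
                                         linkage)$match)
  open_ended <- make_trial(max_age_years = NA_real_)
  expect_true(trial_matches_participant(open_ended, 90, "Female", "372",
                                        "250.2", linkage)$match)
  # (c) sex rules
  male_only <- make_trial(sex_eligibility = "Male")
  expect_false(trial_matches_participant(male_only, 53, "Female", "372",
                                         "250.2", linkage)$match)
  expect_true(trial_matches_participant(male_only, 53, "Male", "372",
                                        "250.2", linkage)$match)
  expect_false(trial_matches_participant(male_only, 53, "Intersex", "372",
                                         "250.2", linkage)$match)
  expect_true(trial_matches_participant(trial, 53, "Intersex", "372",
                                        "250.2", linkage)$match)
  # (d) geography
  expect_false(trial_matches_participant(trial, 53, "Female", "425", "250.2",
                                         linkage)$match)
  # non-recruiting sites do not count toward geography
  closed_site <- make_trial(site_status = "Terminated")
  expect_false(trial_matches_participant(closed_site, 53, "Female", "372",
                                         "250.2", linkage)$match)
})

test_that("match_cohort handles empty registries and empty profiles", {
  map <- tiny_map()
  linkage <- build_condition_linkage(map)
  cov <- make_participant_cov()
  empty <- match_cohort(cov, make_profiles(P1 = "250.2"), list(), linkage)
  expect_equal(empty$counts$total_matches, 0L)
  no_conditions <- match_cohort(cov, make_profiles(),
                                list(make_trial()), linkage)
  expect_equal(no_conditions$counts$total_matches, 0L)
})

test_that("domain and sponsor counts attribute matched trials correctly", {
  map <- tiny_map()
  linkage <- build_condition_linkage(map)
  cov <- make_participant_cov()
  profiles <- make_profiles(P1 = c("250.2", "300.1"))
  trials <- list(
    make_trial("T1", condition_terms = c("type 2 diabetes", "anxiety disorder"),
               sponsor_class = "NIH"),
    make_trial("T2", condition_terms = "anxiety disorder",
               sponsor_class = "Industry"))
  res <- match_cohort(cov, profiles, trials, linkage)
  expect_equal(res$counts$total_matches, 2L)
  # T1 links via both phecodes: counts once in total, once per domain
  expect_equal(res$counts[["domain_Endocrine/Metabolic"]], 1L)
  expect_equal(res$counts$domain_Mental, 2L)
  expect_equal(res$counts$sponsor_NIH, 1L)
  expect_equal(res$counts$sponsor_Industry, 1L)
  expect_equal(sort(res$audit$trial_id), c("T1", "T2"))
  expect_equal(res$audit$linking_phecodes[res$audit$trial_id == "T1"],
               "250.2;300.1")
})

test_that("match_cohort equals the brute-force pairwise oracle on random instances", {
  map <- fixture_map()
  linkage <- build_condition_linkage(map)
  for (s in 1:4) {
    sim <- simulate_cohort(cohort_sim_params(n = 25, map = map, seed = 100 + s))
    reg <- filter_trials(simulate_registry(
      registry_sim_params(n = 60, map = map, seed = 200 + s, contamination = 0.2)))
    prof <- build_condition_profiles(sim$events, map)
    cov <- derive_covariates(sim$cohort, prof$profiles, sim$geo, sim$limits,
                             reference_date = as.Date("2023-02-14"))
    got <- match_cohort(cov, prof$profiles, reg, linkage)$counts
    oracle <- brute_force_counts(cov, prof$profiles, reg, linkage)
    expect_equal(got$total_matches, oracle)
  }
})

test_that("matched counts are monotone in conditions and eligibility", {
  map <- fixture_map()
  linkage <- build_condition_linkage(map)
  sim <- simulate_cohort(cohort_sim_params(n = 40, map = map, seed = 31))
  reg <- filter_trials(simulate_registry(registry_sim_params(n = 80, map = map,
                                                             seed = 32)))
  prof <- build_condition_profiles(sim$events, map)
  cov <- derive_covariates(sim$cohort, prof$profiles, sim$geo, sim$limits,
                           reference_date = as.Date("2023-02-14"))
  full <- match_cohort(cov, prof$profiles, reg, linkage)$counts

  # drop one phecode from every profile: counts never increase
  dropped_ph <- prof$profiles$phecode[1]
  thinner <- prof$profiles[prof$profiles$phecode != dropped_ph, ]
  thin <- match_cohort(cov, thinner, reg, linkage)$counts
  expect_true(all(thin$total_matches <= full$total_matches))

  # widen every trial (all ages 18+, all sexes): counts never decrease
  wide_reg <- lapply(reg, function(tr) {
    tr$min_age_years <- 18; tr$max_age_years <- NA_real_
    tr$sex_eligibility <- "All"
    tr
  })
  wide <- match_cohort(cov, prof$profiles, wide_reg, linkage)$counts
  expect_true(all(wide$total_matches >= full$total_matches))
})

test_that("with all-permissive trials the count is a pure set intersection", {
  map <- fixture_map()
  linkage <- build_condition_linkage(map)
  sim <- simulate_cohort(cohort_sim_params(n = 30, map = map, seed = 41))
  reg <- simulate_registry(registry_sim_params(n = 50, map = map, seed = 42))
  all_zips <- unique(sim$cohort$zip3)
  permissive <- lapply(reg, function(tr) {
    tr$min_age_years <- 18; tr$max_age_years <- NA_real_
    tr$sex_eligibility <- "All"
    tr$sites <- data.frame(zip3 = all_zips, country = "United States",
                           site_status = "Recruiting", stringsAsFactors = FALSE)
    tr
  })
  prof <- build_condition_profiles(sim$events, map)
  cov <- derive_covariates(sim$cohort, prof$profiles, sim$geo, sim$limits,
                           reference_date = as.Date("2023-02-14"))
  got <- match_cohort(cov, prof$profiles, permissive, linkage)$counts
  sets <- split(prof$profiles$phecode[prof$profiles$present],
                prof$profiles$participant_id[prof$profiles$present])
  oracle <- vapply(cov$participant_id, function(pid) {
    present <- sets[[pid]]
    if (is.null(present)) return(0L)
    sum(vapply(permissive, function(tr) {
      length(intersect(link_conditions(tr, linkage), present)) > 0
    }, NA))
  }, 0L)
  expect_equal(got$total_matches, unname(oracle))
})

test_that("stratified means and intervals follow the closed form", {
  counts <- data.table::data.table(participant_id = c("A", "B", "C", "D", "E"),
                                   total_matches = c(2L, 2L, 2L, 0L, 4L))
  cov <- data.table::data.table(participant_id = c("A", "B", "C", "D", "E"),
                                metro = c("M", "M", "M", "N", "N"))
  res <- stratified_mean_matches(counts, cov, "metro")
  m_row <- res[res$level == "M", ]
  expect_equal(m_row$mean, 2.0)
  expect_equal(m_row$ci_low, 2.0)
  expect_equal(m_row$ci_high, 2.0)
  n_row <- res[res$level == "N", ]
  half <- 1.96 * stats::sd(c(0, 4)) / sqrt(2)
  expect_equal(n_row$mean, 2.0)
  expect_equal(n_row$ci_high, 2.0 + half)
  expect_error(stratified_mean_matches(counts, cov, "nope"), "stratifier")
  # singleton levels come back without an interval
  res1 <- stratified_mean_matches(counts[1:3],
                                  cov[1:3][, metro := c("M", "M", "N")], "metro")
  expect_true(is.na(res1$ci_low[res1$level == "N"]))
})

test_that("a planted metro enrichment orders the stratified means", {
  # metro participants carry twice the conditions, hence more matches
  map <- fixture_map()
  linkage <- build_condition_linkage(map)
  sim <- simulate_planted_linkage(n = 200, lambda = 6, seed = 9)
  prof <- build_condition_profiles(sim$events, map = sim$map)
  cov <- derive_covariates(sim$cohort, prof$profiles, sim$geo, sim$limits,
                           reference_date = as.Date("2023-02-14"))
  counts <- match_cohort(cov, prof$profiles, sim$registry,
                         build_condition_linkage(sim$map))$counts
  carrier <- prof$profiles[phecode == sim$truth$planted_phecode & present == TRUE,
                           participant_id]
  cov[, strat := ifelse(participant_id %in% carrier, "carrier", "noncarrier")]
  res <- stratified_mean_matches(counts, cov, "strat")
  expect_gt(res$mean[res$level == "carrier"], res$mean[res$level == "noncarrier"])
})
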