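test_that("intercept-only fit on constant counts is the degenerate ML solution", {
  fit <- suppressWarnings(
    fit_negative_binomial(data.frame(x = rnorm(40)), rep(7L, 40)))
  expect_true(fit$converged)
  expect_equal(fit$coefficients[fit$term_names == "(Intercept)"], log(7),
               tolerance = 1e-6)
  # no overdispersion in constant data: dispersion at the lower boundary
  expect_equal(fit$alpha, 0)
  expect_true(fit$dispersion_boundary)
})

test_that("counts must be non-negative integers", {
  expect_error(fit_negative_binomial(data.frame(x = 1:5), c(1, 2, -1, 0, 3)),
               "non-negative")
  expect_error(fit_negative_binomial(data.frame(x = 1:5), c(1, 2, 0.5, 0, 3)),
               "integer")
})

test_that("the fit agrees with a direct NB2 maximum-likelihood oracle", {
  sim <- simulate_nb_counts(n = 800, intercept = log(12),
                            coef = c(g = log(1.8), z = -0.3),
                            covariate_spec = list(g = list(type = "binary", p = 0.4),
                                                  z = list(type = "normal", mean = 0, sd = 1)),
                            dispersion = 0.8, seed = 14)
  fit <- fit_negative_binomial(sim$design, sim$counts)
  oracle <- nb2_ml_oracle(sim$design, sim$counts)
  expect_equal(fit$coefficients,
               unname(oracle$beta[fit$term_names]), tolerance = 1e-3)
  expect_equal(fit$alpha, oracle$alpha, tolerance = 1e-2)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
})

test_that("Poisson-generated data reproduce a Poisson regression oracle", {
  sim <- simulate_nb_counts(n = 2000, intercept = log(9), coef = c(g = log(1.4)),
                            dispersion = 0, seed = 15)
  fit <- suppressWarnings(fit_negative_binomial(sim$design, sim$counts))
  oracle <- stats::glm(sim$counts ~ g, data = sim$design, family = stats::poisson())
  expect_equal(fit$coefficients[match(c("(Intercept)", "g"), fit$term_names)],
               unname(stats::coef(oracle)), tolerance = 1e-3)
})

test_that("NB log-likelihood is at least the Poisson log-likelihood", {
  for (s in c(23, 24)) {
    sim <- simulate_nb_counts(n = 600, intercept = log(10), coef = c(g = 0.3),
                              dispersion = 1.2, seed = s)
    nb <- fit_negative_binomial(sim$design, sim$counts)
    po <- stats::glm(sim$counts ~ g, data = sim$design, family = stats::poisson())
    expect_gte(nb$loglik, as.numeric(stats::logLik(po)) - 1e-6)
  }
})

test_that("collinear terms are dropped with a warning", {
  sim <- simulate_nb_counts(n = 300, intercept = log(5), coef = c(g = 0.4),
                            dispersion = 0.5, seed = 16)
  design <- sim$design
  design$g2 <- design$g  # exact copy
  expect_warning(fit <- fit_negative_binomial(design, sim$counts), "collinear")
  expect_equal(fit$dropped_terms, "g2")
  expect_false("g2" %in% fit$term_names)
})

test_that("coefficient summaries follow the closed-form Wald construction", {
  fit <- structure(list(term_names = c("(Intercept)", "b"),
                        coefficients = c(1, 0.4055), se = c(0.2, 0.1),
                        alpha = 0.5, theta = 2, loglik = -10, converged = TRUE,
                        n = 100, dispersion_boundary = FALSE,
                        dropped_terms = character()),
                   class = "nb_fit")
  s <- coefficient_summary(fit, "b")
  expect_equal(s$ratio, exp(0.4055))
  expect_equal(s$percent_change, (exp(0.4055) - 1) * 100)
  expect_equal(s$ci_low, exp(0.4055 - 1.96 * 0.1))
  expect_equal(s$ci_high, exp(0.4055 + 1.96 * 0.1))
  z <- 0.4055 / 0.1
  expect_equal(s$p, 2 * stats::pnorm(-z))
  expect_false(s$p_underflow)
  # a ratio of 1.59 is a 59% increase
  fit$coefficients[2] <- log(1.59)
  expect_equal(round(coefficient_summary(fit, "b")$percent_change), 59)
  # null coefficient
  fit$coefficients[2] <- 0
  s0 <- coefficient_summary(fit, "b")
  expect_equal(s0$ratio, 1)
  expect_equal(s0$percent_change, 0)
  expect_error(coefficient_summary(fit, "nope"), "unknown term")
})

test_that("p-values past the floating floor are reported as a flagged bound", {
  fit <- structure(list(term_names = "b", coefficients = 4, se = 0.1,
                        alpha = 0.5, theta = 2, loglik = -10, converged = TRUE,
                        n = 1e5, dispersion_boundary = FALSE,
                        dropped_terms = character()),
                   class = "nb_fit")
  s <- coefficient_summary(fit, "b")  # z = 40 underflows double precision
  expect_true(s$p_underflow)
  expect_equal(s$p, 1e-300)
  expect_gt(s$neglog10_p, 300)
})

test_that("presence-indicator recoding flips the ratio to its reciprocal", {
  sim <- simulate_nb_counts(n = 1000, intercept = log(8), coef = c(g = 0.5),
                            dispersion = 0.7, seed = 17)
  f1 <- fit_negative_binomial(sim$design, sim$counts)
  flipped <- data.frame(g = 1 - sim$design$g)
  f2 <- fit_negative_binomial(flipped, sim$counts)
  r1 <- exp(f1$coefficients[f1$term_names == "g"])
  r2 <- exp(f2$coefficients[f2$term_names == "g"])
  expect_equal(r1, 1 / r2, tolerance = 1e-6)
})

test_that("the Bonferroni threshold is alpha/m and decreasing in m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 500), 1e-4)
  expect_true(4e-5 < bonferroni_threshold(0.05, 500))
  ms <- c(1, 2, 5, 10, 100)
  expect_true(all(diff(vapply(ms, function(m) bonferroni_threshold(0.05, m), 1)) < 0))
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("the phenome-wide scan applies the case floor and sorts by p", {
  map <- fixture_map()
  sim <- simulate_cohort(cohort_sim_params(n = 250, map = map, seed = 71))
  prof <- build_condition_profiles(sim$events, map)
  cov <- derive_covariates(sim$cohort, prof$profiles, sim$geo, sim$limits,
                           reference_date = as.Date("2023-02-14"))
  counts <- data.table::data.table(participant_id = cov$participant_id,
                                   total_matches = rpois(nrow(cov), 10))
  pw <- run_phewas(cov, prof$profiles, counts, map, min_cases = 20)
  expect_true(all(pw$results$n_cases >= 20))
  expect_true(all(pw$skipped$n_cases < 20))
  expect_equal(pw$m, nrow(pw$results))
  expect_equal(pw$threshold, 0.05 / pw$m)
  expect_false(is.unsorted(pw$results$p))
  expect_equal(pw$results$significant, pw$results$p < pw$threshold)
})

test_that("the SDoH analysis uses the declared reference levels", {
  map <- fixture_map()
  sim <- simulate_cohort(cohort_sim_params(n = 300, map = map, seed = 81,
                                           missing_disability = 0,
                                           missing_income = 0,
                                           missing_education = 0,
                                           missing_sdoh = 0))
  prof <- build_condition_profiles(sim$events, map)
  cov <- derive_covariates(sim$cohort, prof$profiles, sim$geo, sim$limits,
                           reference_date = as.Date("2023-02-14"))
  counts <- data.table::data.table(
    participant_id = cov$participant_id,
    total_matches = rpois(nrow(cov), 8),
    domain_Mental = rpois(nrow(cov), 3))
  sd <- run_sdoh(cov, counts)
  refs <- sd$results[sd$results$reference, ]
  expected_refs <- c(race_ethnicity = "White", sex_at_birth = "Female",
                     metro = "Metropolitan", housing_quality = "Good",
                     low_income = "No", food_insecurity = "No",
                     education = "11orBelow", english_proficient = "No")
  for (v in names(expected_refs)) {
    expect_equal(unique(refs$level[refs$covariate == v]), unname(expected_refs[v]))
  }
  expect_true(all(refs$ratio == 1))
  expect_true(all(is.na(refs$ci_low)))
  expect_setequal(unique(sd$results$outcome), c("Total", "Mental"))
})

test_that("a planted metro effect is recovered by the SDoH model", {
  # nonmetro counts generated at 1/8 the metro mean, dispersion 1
  set.seed(91)
  n <- 4000
  metro <- rbinom(n, 1, 0.7)
  mu <- ifelse(metro == 1, 24, 3)
  cov <- data.table::data.table(
    participant_id = sprintf("P%05d", 1:n),
    age_years = sample(20:80, n, TRUE),
    sex_at_birth = sample(c("Male", "Female"), n, TRUE),
    race_ethnicity = sample(c("White", "Black"), n, TRUE),
    metro = ifelse(metro == 1, "Metropolitan", "Nonmetropolitan"),
    low_income = sample(c("Yes", "No"), n, TRUE),
    education = sample(c("11orBelow", "12orGED"), n, TRUE),
    english_proficient = "Yes", food_insecurity = "No",
    discrimination_score = 2, social_support_score = 3,
    housing_quality = "Good", neighborhood_cohesion_score = 3,
    n_conditions = rpois(n, 4))
  counts <- data.table::data.table(
    participant_id = cov$participant_id,
    total_matches = rnbinom(n, size = 1, mu = mu))
  sd <- suppressWarnings(run_sdoh(cov, counts))
  row <- sd$results[sd$results$covariate == "metro" &
                      sd$results$level == "Nonmetropolitan", ]
  # metro-vs-nonmetro ratio: reciprocal of the nonmetro coefficient
  ratio <- 1 / row$ratio
  expect_gt(ratio, 6)
  expect_lt(ratio, 10.7)
  expect_true(row$significant)
})

test_that("single-level covariates are dropped with a warning", {
  sim <- simulate_nb_counts(n = 200, intercept = log(6), coef = c(g = 0.3),
                            dispersion = 0.5, seed = 18)
  design <- sim$design
  design$constant <- "OnlyLevel"
  expect_warning(fit <- fit_negative_binomial(design, sim$counts),
                 "single-level")
  expect_false(any(grepl("constant", fit$term_names)))
})

test_that("the Manhattan export caps, flags, and labels correctly", {
  res <- data.frame(
    phecode = c("a", "b", "c"), condition = c("A", "B", "C"),
    domain = "Other", n_cases = 30,
    ratio = c(2, 1.5, 1), ci_low = 1, ci_high = 3,
    percent_change = c(100, 50, 0),
    p = c(1e-300, 1e-10, 0.5), p_underflow = c(TRUE, FALSE, FALSE),
    neglog10_p = c(320, 10, 0.301), significant = c(TRUE, TRUE, FALSE))
  pw <- list(results = res, m = 3, threshold = 0.05 / 3)
  man <- manhattan_export(pw, top_k = 2)
  expect_equal(man$neglog10_p, c(300, 10, 0.301))
  expect_equal(man$p_underflow, c(TRUE, FALSE, FALSE))
  expect_equal(man$threshold_line, rep(-log10(0.05 / 3), 3))
  expect_equal(man$label, c(TRUE, TRUE, FALSE))
})
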