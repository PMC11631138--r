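# Shared fixture builders: everything is constructed in code at test time.

fixture_map_path <- function() {
  system.file("extdata", "phecode_map_synthetic.csv", package = "trialopps")
}

fixture_map <- function() read_phecode_map(fixture_map_path())

# small hand-held map: two phecodes in two domains
tiny_map <- function() {
  as_phecode_map(data.frame(
    icd_code = c("E11.9", "250.00", "F41.9"),
    vocabulary = c("ICD10CM", "ICD9CM", "ICD10CM"),
    phecode = c("250.2", "250.2", "300.1"),
    description = c("type 2 diabetes", "type 2 diabetes", "anxiety disorder"),
    domain = c("endocrine/metabolic", "endocrine/metabolic", "mental disorders"),
    stringsAsFactors = FALSE))
}

make_trial <- function(trial_id = "NCT00000001",
                       overall_status = "Recruiting",
                       study_type = "Interventional",
                       min_age_years = 18, max_age_years = 65,
                       sex_eligibility = "All",
                       condition_terms = "type 2 diabetes",
                       zips = "372", countries = "United States",
                       site_status = "Recruiting",
                       sponsor_class = "NIH") {
  n <- length(zips)
  trialopps:::new_trial_record(
    trial_id = trial_id, overall_status = overall_status,
    study_type = study_type, min_age_years = min_age_years,
    max_age_years = max_age_years, sex_eligibility = sex_eligibility,
    condition_terms = condition_terms,
    sites = data.frame(zip3 = zips, country = rep_len(countries, n),
                       site_status = rep_len(site_status, n),
                       stringsAsFactors = FALSE),
    sponsor_class = sponsor_class)
}

toy_geo <- function() {
  data.frame(zip3 = c("372", "425"),
             metro_flag = c("Metropolitan", "Nonmetropolitan"),
             stringsAsFactors = FALSE)
}

# covariate row builder for matching tests
make_participant_cov <- function(participant_id = "P1", age_years = 53,
                                 sex_at_birth = "Female", zip3 = "372") {
  data.table::data.table(participant_id = participant_id,
                         age_years = age_years,
                         sex_at_birth = sex_at_birth, zip3 = zip3)
}

make_profiles <- function(...) {
  # make_profiles(P1 = c("250.2"), P2 = character())
  sets <- list(...)
  rows <- lapply(names(sets), function(pid) {
    if (length(sets[[pid]]) == 0L) return(NULL)
    data.table::data.table(participant_id = pid, phecode = sets[[pid]],
                           n_instances = 2L, present = TRUE)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(participant_id = character(),
                                  phecode = character(),
                                  n_instances = integer(), present = logical())
  }
  out
}

# independent brute-force matcher: literal per-pair rule evaluation, kept
# deliberately naive and separate from match_cohort's internals
brute_force_counts <- function(covariates, profiles, registry, linkage) {
  sets <- split(profiles$phecode[profiles$present], profiles$participant_id[profiles$present])
  vapply(seq_len(nrow(covariates)), function(i) {
    pid <- covariates$participant_id[i]
    present <- sets[[pid]]
    if (is.null(present)) return(0L)
    n <- 0L
    for (tr in registry) {
      res <- trial_matches_participant(tr, covariates$age_years[i],
                                       covariates$sex_at_birth[i],
                                       covariates$zip3[i], present, linkage)
      if (res$match) n <- n + 1L
    }
    n
  }, 0L)
}

# independent NB2 maximum-likelihood oracle: direct optim over (beta, log alpha)
nb2_ml_oracle <- function(X, y, init_beta = NULL) {
  X <- as.matrix(cbind(`(Intercept)` = 1, X))
  nll <- function(par) {
    beta <- par[seq_len(ncol(X))]
    alpha <- exp(par[ncol(X) + 1L])
    mu <- exp(drop(X %*% beta))
    -sum(lgamma(y + 1 / alpha) - lgamma(1 / alpha) - lgamma(y + 1) +
           y * log(alpha * mu / (1 + alpha * mu)) -
           (1 / alpha) * log(1 + alpha * mu))
  }
  init <- c(init_beta %||% c(log(mean(y) + 0.5), rep(0, ncol(X) - 1L)), 0)
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(beta = stats::setNames(opt$par[seq_len(ncol(X))], colnames(X)),
       alpha = exp(opt$par[ncol(X) + 1L]),
       loglik = -opt$value)
}
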