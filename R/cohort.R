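# Participant data model: reading cohort tables, deriving analysis covariates
# (metro status, low-income flag, age, condition count), and the Table-1-style
# cohort summary.

RACE_LEVELS <- c("White", "Black", "Hispanic", "Asian", "MENA", "NHOPI",
                 "Multiple", "Remaining")
EDUCATION_LEVELS <- c("11orBelow", "12orGED", "CollegeGrad", "AdvancedDegree")
SEX_LEVELS <- c("Male", "Female", "Intersex", "Unknown")

#' Read a cohort table
#'
#' One row per participant. Expected columns: `participant_id`, `birth_year`,
#' `sex_at_birth`, `race_ethnicity`, `zip3`, `education`, `household_size`,
#' `annual_income`, `disability`, and the SDoH columns `english_proficient`,
#' `food_insecurity`, `discrimination_score`, `social_support_score`,
#' `housing_quality`, `neighborhood_cohesion_score`. Missing values are empty
#' cells.
#'
#' @param path CSV path.
#' @return data.table of participants.
#' @export
read_cohort <- function(path) {
  ch <- data.table::fread(path, colClasses = list(character = c("participant_id", "zip3")),
                          na.strings = c("", "NA"))
  needed <- c("participant_id", "birth_year", "sex_at_birth", "race_ethnicity",
              "zip3", "education", "household_size", "annual_income", "disability")
  missing_cols <- setdiff(needed, names(ch))
  if (length(missing_cols)) {
    stop("cohort table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  assert_zip3(ch$zip3)
  ch[]
}

#' Read the zip3 geography lookup
#'
#' CSV with columns `zip3`, `metro_flag` (values `Metropolitan` /
#' `Nonmetropolitan`), emulating a USDA rural-urban classification collapsed
#' to zip3 resolution.
#'
#' @param path CSV path.
#' @return data.frame lookup.
#' @export
read_geo_lookup <- function(path) {
  geo <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("zip3", "metro_flag") %in% names(geo)))
  bad <- !geo$metro_flag %in% c("Metropolitan", "Nonmetropolitan")
  if (any(bad)) stop("geo lookup: metro_flag must be Metropolitan/Nonmetropolitan",
                     call. = FALSE)
  geo
}

#' Read the income-limits lookup
#'
#' CSV keyed on (`zip3`, `household_size`, `fiscal_year`) with the low-income
#' limit in `income_limit`, emulating household-size- and area-specific
#' low-income limits.
#'
#' @param path CSV path.
#' @return data.table keyed for lookup.
#' @export
read_income_limits <- function(path) {
  lim <- data.table::fread(path, colClasses = list(character = "zip3"))
  stopifnot(all(c("zip3", "household_size", "fiscal_year", "income_limit") %in% names(lim)))
  data.table::setkey(lim, zip3, household_size, fiscal_year)
  lim[]
}

#' Classify a zip3 as metropolitan or nonmetropolitan
#'
#' Deterministic lookup; zip3s missing from the table return `NA` and should
#' flag the participant for exclusion from location-adjusted analyses.
#'
#' @param zip3 Character vector of 3-digit zip prefixes.
#' @param geo Geography lookup (see [read_geo_lookup()]).
#' @return Character vector: `"Metropolitan"`, `"Nonmetropolitan"`, or `NA`.
#' @export
classify_metro <- function(zip3, geo) {
  assert_zip3(zip3)
  unname(stats::setNames(geo$metro_flag, geo$zip3)[zip3])
}

#' Classify a participant as low income
#'
#' Low income when annual household income does not exceed the limit for the
#' participant's zip3, household size, and fiscal year. Returns `NA` when
#' income, household size, or the limit itself is unavailable.
#'
#' @param annual_income,household_size Numeric vectors.
#' @param zip3 Character vector.
#' @param fiscal_year Integer (scalar or vector).
#' @param limits Income-limits lookup (see [read_income_limits()]).
#' @return Character vector `"Yes"`/`"No"`/`NA`.
#' @export
classify_low_income <- function(annual_income, household_size, zip3,
                                fiscal_year, limits) {
  n <- max(length(annual_income), length(household_size), length(zip3),
           length(fiscal_year))
  annual_income <- rep_len(annual_income, n)
  household_size <- rep_len(household_size, n)
  zip3 <- rep_len(zip3, n)
  fiscal_year <- rep_len(as.integer(fiscal_year), n)
  q <- data.table::data.table(zip3 = zip3,
                              household_size = as.integer(household_size),
                              fiscal_year = fiscal_year)
  lim <- limits[q, on = c("zip3", "household_size", "fiscal_year")]$income_limit
  ifelse(is.na(annual_income) | is.na(household_size) | is.na(lim), NA_character_,
         ifelse(annual_income <= lim, "Yes", "No"))
}

#' Derive the analysis covariates for a cohort
#'
#' Computes age at the reference date from birth year (reference year minus
#' birth year), the under-50/50-plus age group, metro classification,
#' low-income flag, and the number of present conditions, and carries the
#' remaining self-reported covariates through. Participants younger than 18
#' or with an unknown zip3 classification are flagged for exclusion from
#' analysis sets.
#'
#' @param cohort Cohort table (see [read_cohort()]).
#' @param profiles Condition profiles data.table from
#'   [build_condition_profiles()].
#' @param geo Geography lookup.
#' @param limits Income-limits lookup.
#' @param reference_date Date at which age is evaluated (default: today).
#' @param fiscal_year Fiscal year for the low-income lookup (default: year of
#'   `reference_date`).
#' @return data.table of covariate vectors, one row per participant, with
#'   logical columns `underage` and `metro_missing`.
#' @export
derive_covariates <- function(cohort, profiles, geo, limits,
                              reference_date = Sys.Date(),
                              fiscal_year = NULL) {
  ref <- as_ref_date(reference_date)
  ref_year <- as.integer(format(ref, "%Y"))
  fiscal_year <- fiscal_year %||% ref_year
  cv <- data.table::as.data.table(cohort)
  cv <- cv[, .(participant_id, birth_year, sex_at_birth, race_ethnicity, zip3,
               education, household_size, annual_income, disability,
               english_proficient = if ("english_proficient" %in% names(cv)) english_proficient else NA_character_,
               food_insecurity = if ("food_insecurity" %in% names(cv)) food_insecurity else NA_character_,
               discrimination_score = if ("discrimination_score" %in% names(cv)) discrimination_score else NA_real_,
               social_support_score = if ("social_support_score" %in% names(cv)) social_support_score else NA_real_,
               housing_quality = if ("housing_quality" %in% names(cv)) housing_quality else NA_character_,
               neighborhood_cohesion_score = if ("neighborhood_cohesion_score" %in% names(cv)) neighborhood_cohesion_score else NA_real_)]
  cv[, age_years := ref_year - as.integer(birth_year)]
  cv[, age_group := ifelse(age_years >= 50, "50Plus", "Under50")]
  cv[, underage := !is.na(age_years) & age_years < 18]
  cv[, metro := classify_metro(zip3, geo)]
  cv[, metro_missing := is.na(metro)]
  cv[, low_income := classify_low_income(annual_income, household_size, zip3,
                                         fiscal_year, limits)]
  ncond <- profiles[profiles$present == TRUE,
                    .(n_conditions = .N), by = participant_id]
  cv <- ncond[cv, on = "participant_id"]
  cv[is.na(n_conditions), n_conditions := 0L]
  data.table::setcolorder(cv, "participant_id")
  cv[]
}

summary_block <- function(values, levels, full_denominator, n_full) {
  x <- as.character(values)
  denom <- if (full_denominator) n_full else sum(!is.na(x))
  rows <- lapply(levels, function(l) {
    n <- sum(x == l, na.rm = TRUE)
    data.frame(level = l, n = n,
               pct = if (denom > 0) round(100 * n / denom, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort summary table
#'
#' Counts and percentages (one decimal place) per level of each
#' sociodemographic variable, and per consolidated condition domain the
#' number of participants with at least one present phecode in the domain
#' (participants can count toward several domains). Percentages for age,
#' sex, race/ethnicity, and geography use the full cohort as denominator;
#' education, disability, and low income use the non-missing responses for
#' that variable.
#'
#' @param covariates Covariate table from [derive_covariates()].
#' @param profiles Condition profiles data.table.
#' @param map A `phecode_map` (for phecode -> domain).
#' @return data.frame with columns `variable`, `level`, `n`, `pct`.
#' @export
cohort_summary <- function(covariates, profiles, map) {
  cv <- data.table::as.data.table(covariates)
  if (nrow(cv) == 0L) stop("empty cohort", call. = FALSE)
  n_full <- nrow(cv)
  blocks <- list(
    age_group = list(cv$age_group, c("Under50", "50Plus"), TRUE),
    sex_at_birth = list(cv$sex_at_birth, intersect(SEX_LEVELS, unique(cv$sex_at_birth)), TRUE),
    race_ethnicity = list(cv$race_ethnicity, intersect(RACE_LEVELS, unique(cv$race_ethnicity)), TRUE),
    geography = list(cv$metro, c("Metropolitan", "Nonmetropolitan"), TRUE),
    education = list(cv$education, intersect(EDUCATION_LEVELS, unique(cv$education)), FALSE),
    disability = list(cv$disability, c("Yes", "No"), FALSE),
    low_income = list(cv$low_income, c("Yes", "No"), FALSE))
  out <- do.call(rbind, lapply(names(blocks), function(v) {
    b <- blocks[[v]]
    cbind(variable = v, summary_block(b[[1]], b[[2]], b[[3]], n_full))
  }))
  pr <- data.table::as.data.table(profiles)[present == TRUE]
  pr[, domain := unname(map$domains[phecode])]
  dom <- pr[!is.na(domain), .(n = data.table::uniqueN(participant_id)), by = domain]
  dom_rows <- do.call(rbind, lapply(consolidated_domains(), function(d) {
    n <- dom$n[match(d, dom$domain)]
    n <- if (is.na(n)) 0L else n
    data.frame(variable = "condition_domain", level = d, n = n,
               pct = round(100 * n / n_full, 1), stringsAsFactors = FALSE)
  }))
  rbind(out, dom_rows)
}
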