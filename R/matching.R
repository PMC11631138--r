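# The core computation: participant-trial eligibility on condition, age, sex
# at birth, and zip3 geography, and matched-trial counts per participant.

#' Build a condition linkage from a phecode map
#'
#' The linkage resolves normalized trial condition terms to phecodes: the
#' normalized phecode descriptions, plus an optional synonym table for
#' alternative names. Matching is exact on the normalized string — no fuzzy
#' or substring matching — so every link is auditable; the synonym table is
#' the extension point.
#'
#' @param map A `phecode_map`.
#' @param synonyms Optional named character vector: synonym term -> phecode.
#' @return A `condition_linkage` object.
#' @export
build_condition_linkage <- function(map, synonyms = NULL) {
  terms <- stats::setNames(names(map$phecodes), normalize_term(map$phecodes))
  if (!is.null(synonyms)) {
    syn <- stats::setNames(unname(synonyms), normalize_term(names(synonyms)))
    terms <- c(terms, syn)
  }
  structure(list(terms = terms, domains = map$domains), class = "condition_linkage")
}

#' Phecodes linked to a trial's condition terms
#'
#' Union over the trial's condition terms of exact normalized-string hits in
#' the linkage; the empty set when nothing links.
#'
#' @param trial A trial record.
#' @param linkage A `condition_linkage`.
#' @return Character vector of phecodes (possibly empty).
#' @export
link_conditions <- function(trial, linkage) {
  hits <- linkage$terms[normalize_term(trial$condition_terms)]
  sort(unique(hits[!is.na(hits)]))
}

sex_compatible <- function(trial_sex, participant_sex) {
  if (trial_sex == "All") return(TRUE)
  if (is.na(participant_sex)) return(FALSE)
  participant_sex %in% c("Male", "Female") && participant_sex == trial_sex
}

#' Does a trial match a participant?
#'
#' A match requires all four rules: (a) at least one of the trial's linked
#' phecodes is present in the participant's condition profile; (b) the
#' participant's age is at least the trial's minimum age and, when a maximum
#' age is stated, at most that; (c) sex eligibility `All` matches any sex at
#' birth, `Male`/`Female` match the same sex, and intersex or unknown sex
#' matches only `All`; (d) the participant's zip3 equals the zip3 of at
#' least one eligible US site.
#'
#' @param trial A trial record (already passed [filter_trials()]).
#' @param age_years Participant age in years.
#' @param sex_at_birth Participant sex at birth.
#' @param zip3 Participant zip3.
#' @param present Character vector of present phecodes.
#' @param linkage A `condition_linkage`.
#' @param linked Optional precomputed [link_conditions()] result.
#' @return List with `match` (logical) and `linking_phecodes`.
#' @export
trial_matches_participant <- function(trial, age_years, sex_at_birth, zip3,
                                      present, linkage, linked = NULL) {
  linked <- linked %||% link_conditions(trial, linkage)
  linking <- intersect(linked, present)
  ok <- length(linking) > 0L &&
    !is.na(age_years) &&
    !is.na(trial$min_age_years) && age_years >= trial$min_age_years &&
    (is.na(trial$max_age_years) || age_years <= trial$max_age_years) &&
    sex_compatible(trial$sex_eligibility, sex_at_birth) &&
    zip3 %in% eligible_us_sites(trial)$zip3
  list(match = ok, linking_phecodes = if (ok) linking else character())
}

#' Match a cohort against a filtered registry
#'
#' For every participant, the deduplicated set of matching trials with the
#' phecodes that linked each one, and derived counts: total, per consolidated
#' condition domain (a trial counts once toward each distinct domain among
#' its linking phecodes), and per sponsor class.
#'
#' @param covariates Covariate table from [derive_covariates()] (needs
#'   `participant_id`, `age_years`, `sex_at_birth`, `zip3`).
#' @param profiles Condition profiles data.table.
#' @param registry List of filtered trial records.
#' @param linkage A `condition_linkage`.
#' @return List with `counts` (data.table: `participant_id`,
#'   `total_matches`, one `domain_*` column per consolidated domain, one
#'   `sponsor_*` column per sponsor class) and `audit` (data.table:
#'   `participant_id`, `trial_id`, `linking_phecodes` as a
#'   semicolon-separated string).
#' @export
match_cohort <- function(covariates, profiles, registry, linkage) {
  cv <- data.table::as.data.table(covariates)
  sets <- present_sets(profiles)
  domains <- consolidated_domains()
  sponsors <- sort(unique(vapply(registry, `[[`, "", "sponsor_class")))

  # precompute per-trial: linked phecodes, their domains, eligible site zips
  trial_info <- lapply(registry, function(tr) {
    linked <- link_conditions(tr, linkage)
    list(trial_id = tr$trial_id,
         linked = linked,
         linked_domains = unique(unname(linkage$domains[linked])),
         min_age = tr$min_age_years,
         max_age = tr$max_age_years,
         sex = tr$sex_eligibility,
         zips = unique(eligible_us_sites(tr)$zip3),
         sponsor = tr$sponsor_class)
  })

  count_rows <- vector("list", nrow(cv))
  audit_rows <- vector("list", nrow(cv))
  for (i in seq_len(nrow(cv))) {
    pid <- cv$participant_id[i]
    present <- sets[[pid]] %||% character()
    age <- cv$age_years[i]
    sex <- cv$sex_at_birth[i]
    zip <- cv$zip3[i]
    dom_hit <- stats::setNames(integer(length(domains)), domains)
    spon_hit <- stats::setNames(integer(length(sponsors)), sponsors)
    matched_ids <- character()
    linking_str <- character()
    if (length(present) > 0L && !is.na(age)) {
      for (ti in trial_info) {
        linking <- intersect(ti$linked, present)
        if (length(linking) == 0L) next
        if (is.na(ti$min_age) || age < ti$min_age) next
        if (!is.na(ti$max_age) && age > ti$max_age) next
        if (!sex_compatible(ti$sex, sex)) next
        if (!zip %in% ti$zips) next
        matched_ids <- c(matched_ids, ti$trial_id)
        linking_str <- c(linking_str, paste(linking, collapse = ";"))
        d <- unique(unname(linkage$domains[linking]))
        dom_hit[d] <- dom_hit[d] + 1L
        spon_hit[ti$sponsor] <- spon_hit[ti$sponsor] + 1L
      }
    }
    row <- c(list(participant_id = pid, total_matches = length(matched_ids)),
             as.list(stats::setNames(dom_hit, paste0("domain_", domains))),
             if (length(sponsors))
               as.list(stats::setNames(spon_hit, paste0("sponsor_", sponsors))))
    count_rows[[i]] <- row
    audit_rows[[i]] <- if (length(matched_ids)) {
      data.table::data.table(participant_id = pid, trial_id = matched_ids,
                             linking_phecodes = linking_str)
    }
  }
  counts <- data.table::rbindlist(count_rows)
  audit <- data.table::rbindlist(audit_rows[!vapply(audit_rows, is.null, NA)])
  if (nrow(audit) == 0L) {
    audit <- data.table::data.table(participant_id = character(),
                                    trial_id = character(),
                                    linking_phecodes = character())
  }
  list(counts = counts, audit = audit)
}

#' Mean matched trials stratified by a covariate
#'
#' Per level of the stratifier: the mean matched-trial count and a normal
#' 95% interval, mean plus/minus 1.96 times the standard error of the mean.
#' Levels with fewer than two participants are reported without an interval.
#'
#' @param counts Count table from [match_cohort()].
#' @param covariates Covariate table.
#' @param stratifier Name of a covariate column.
#' @param outcome `"total"` or a consolidated domain name.
#' @return data.frame: `level`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
stratified_mean_matches <- function(counts, covariates, stratifier,
                                    outcome = "total") {
  cv <- data.table::as.data.table(covariates)
  if (!stratifier %in% names(cv)) {
    stop("unknown stratifier: ", stratifier, call. = FALSE)
  }
  col <- if (identical(outcome, "total")) "total_matches" else paste0("domain_", outcome)
  if (!col %in% names(counts)) stop("unknown outcome: ", outcome, call. = FALSE)
  dt <- merge(data.table::as.data.table(counts)[, c("participant_id", col), with = FALSE],
              cv[, c("participant_id", stratifier), with = FALSE],
              by = "participant_id")
  data.table::setnames(dt, c(col, stratifier), c("value", "level"))
  dt <- dt[!is.na(level)]
  res <- dt[, {
    m <- mean(value)
    s <- stats::sd(value)
    half <- if (.N >= 2L) 1.96 * s / sqrt(.N) else NA_real_
    .(n = .N, mean = m, ci_low = m - half, ci_high = m + half)
  }, by = level]
  as.data.frame(res[order(level)])
}
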