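# ICD event streams -> phecode condition profiles under the rule-of-two, plus
# consolidation of phecode domains into the seven analysis domains.

#' Consolidated condition domains
#' @return Character vector of the seven analysis domains.
#' @export
consolidated_domains <- function() {
  c("Mental", "Cancer", "Neurological", "Endocrine/Metabolic",
    "Circulatory", "Respiratory", "Other")
}

# raw phecode domain label -> consolidated analysis domain
DOMAIN_CONSOLIDATION <- c(
  "mental disorders" = "Mental",
  "neoplasms" = "Cancer",
  "neurological" = "Neurological",
  "endocrine/metabolic" = "Endocrine/Metabolic",
  "circulatory system" = "Circulatory",
  "respiratory" = "Respiratory",
  "digestive" = "Other",
  "hematopoietic" = "Other",
  "sense organs" = "Other",
  "symptoms" = "Other",
  "musculoskeletal" = "Other",
  "genitourinary" = "Other",
  "injuries & poisoning" = "Other",
  "injuries & poisonings" = "Other",
  "pregnancy complications" = "Other",
  "dermatologic" = "Other",
  "congenital anomalies" = "Other",
  "infectious diseases" = "Other")

#' Consolidate a raw phecode domain label
#'
#' The six domains with the most trials (mental, neoplasms, neurological,
#' endocrine/metabolic, circulatory, respiratory) map to themselves; every
#' other phecode domain maps to `"Other"`. Labels already in consolidated form
#' pass through.
#'
#' @param domain Character vector of raw phecode domain labels.
#' @return Character vector of consolidated domains.
#' @export
#' @examples
#' consolidate_domain(c("mental disorders", "digestive", "neoplasms"))
consolidate_domain <- function(domain) {
  key <- tolower(trimws(domain))
  out <- unname(DOMAIN_CONSOLIDATION[key])
  # already-consolidated labels are accepted verbatim
  pass <- is.na(out) & domain %in% consolidated_domains()
  out[pass] <- domain[pass]
  if (anyNA(out)) {
    bad <- unique(domain[is.na(out)])
    stop("unknown phecode domain label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(names(DOMAIN_CONSOLIDATION), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read an ICD-to-phecode map
#'
#' CSV with columns `icd_code`, `vocabulary`, `phecode`, `description`,
#' `domain`. Every phecode must carry a description and a known domain; the
#' domain column may hold raw phecode domain labels or consolidated ones.
#'
#' @param path CSV path.
#' @return A `phecode_map`: data.frame plus a lookup environment.
#' @export
read_phecode_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  needed <- c("icd_code", "vocabulary", "phecode", "description", "domain")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("phecode map missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as_phecode_map(df)
}

#' Build a phecode map from a data.frame
#'
#' @param df Data.frame with columns `icd_code`, `vocabulary`, `phecode`,
#'   `description`, `domain`.
#' @return A `phecode_map` object.
#' @export
as_phecode_map <- function(df) {
  if (any(!nzchar(df$description))) {
    stop("phecode map: every phecode needs a description", call. = FALSE)
  }
  df$domain_consolidated <- consolidate_domain(df$domain)
  lookup <- new.env(parent = emptyenv())
  key <- paste(df$icd_code, df$vocabulary, sep = "\r")
  for (i in seq_len(nrow(df))) assign(key[i], df$phecode[i], envir = lookup)
  ph <- df[!duplicated(df$phecode), c("phecode", "description", "domain_consolidated")]
  structure(list(table = df,
                 lookup = lookup,
                 phecodes = stats::setNames(ph$description, ph$phecode),
                 domains = stats::setNames(ph$domain_consolidated, ph$phecode)),
            class = "phecode_map")
}

#' Map ICD codes to phecodes
#'
#' Exact (code, vocabulary) lookup; unmapped codes return `NA`.
#'
#' @param code,vocabulary Character vectors (recycled to common length).
#' @param map A `phecode_map`.
#' @return Character vector of phecodes, `NA` where unmapped.
#' @export
map_icd_to_phecode <- function(code, vocabulary, map) {
  stopifnot(inherits(map, "phecode_map"))
  key <- paste(code, vocabulary, sep = "\r")
  vapply(key, function(k) {
    if (exists(k, envir = map$lookup, inherits = FALSE))
      get(k, envir = map$lookup) else NA_character_
  }, "", USE.NAMES = FALSE)
}

#' Read an ICD events table
#'
#' CSV with columns `participant_id`, `code`, `vocabulary`, `date` (ISO-8601).
#'
#' @param path CSV path.
#' @return data.table of events.
#' @export
read_icd_events <- function(path) {
  ev <- data.table::fread(path, colClasses = list(character = c("participant_id", "code", "vocabulary")))
  needed <- c("participant_id", "code", "vocabulary", "date")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols)) {
    stop("events table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ev[, date := as.Date(date)]
  if (anyNA(ev$date)) stop("events table: invalid date(s)", call. = FALSE)
  ev[]
}

#' Build condition profiles from an ICD event stream
#'
#' An instance of a condition is a distinct event date carrying any ICD code
#' that maps to the condition's phecode; a condition is present when a
#' participant has at least `min_instances` instances (the rule-of-two at the
#' default). With `distinct_dates = FALSE` raw event rows are counted
#' instead.
#'
#' @param events data.table/data.frame of ICD events (`participant_id`,
#'   `code`, `vocabulary`, `date`).
#' @param map A `phecode_map`.
#' @param min_instances Minimum qualifying instances for presence (default 2).
#' @param distinct_dates Count distinct event dates per phecode (default)
#'   rather than raw rows.
#' @return List with `profiles` (data.table `participant_id`, `phecode`,
#'   `n_instances`, `present`) and `coverage` (list: `n_events`, `n_mapped`,
#'   `mapped_fraction`, `unmapped_codes`).
#' @export
build_condition_profiles <- function(events, map, min_instances = 2L,
                                     distinct_dates = TRUE) {
  stopifnot(min_instances >= 1L)
  ev <- data.table::as.data.table(events)
  ev[, phecode := map_icd_to_phecode(code, vocabulary, map)]
  n_events <- nrow(ev)
  unmapped <- ev[is.na(phecode)]
  mapped <- ev[!is.na(phecode)]
  counts <- if (distinct_dates) {
    mapped[, .(n_instances = data.table::uniqueN(date)),
           by = .(participant_id, phecode)]
  } else {
    mapped[, .(n_instances = .N), by = .(participant_id, phecode)]
  }
  counts[, present := n_instances >= min_instances]
  data.table::setkey(counts, participant_id, phecode)
  list(profiles = counts[],
       coverage = list(
         n_events = n_events,
         n_mapped = nrow(mapped),
         mapped_fraction = if (n_events > 0) nrow(mapped) / n_events else NA_real_,
         unmapped_codes = sort(unique(unmapped$code))))
}

#' Condition profile for a single participant
#'
#' Convenience wrapper around [build_condition_profiles()] for one
#' participant's events.
#'
#' @inheritParams build_condition_profiles
#' @return List with `participant_id`, `instance_counts` (named integer
#'   vector by phecode), and `present` (character vector of phecodes).
#' @export
build_condition_profile <- function(events, map, min_instances = 2L,
                                    distinct_dates = TRUE) {
  ids <- unique(events$participant_id)
  if (length(ids) > 1L) {
    stop("events for a single profile must share one participant_id; got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  res <- build_condition_profiles(events, map, min_instances, distinct_dates)
  p <- res$profiles
  list(participant_id = if (length(ids)) ids else NA_character_,
       instance_counts = stats::setNames(p$n_instances, p$phecode),
       present = p$phecode[p$present])
}

# named list: participant_id -> character vector of present phecodes
present_sets <- function(profiles) {
  pr <- profiles[profiles$present == TRUE, ]
  split(pr$phecode, pr$participant_id)
}
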