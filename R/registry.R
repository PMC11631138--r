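# Offline trial-registry snapshots: reading, validation, and the recruiting /
# interventional / adult / US-site filter applied before any matching.

REGISTRY_REQUIRED_KEYS <- c("NCTId", "OverallStatus", "StudyType", "Gender",
                            "Condition", "LeadSponsorClass")

#' Default sponsor-class mapping
#'
#' Maps raw registry lead-sponsor classes onto the four analysis classes.
#' Unlisted raw values fall through to `"Unknown"`.
#'
#' @return Named character vector: raw class -> analysis class.
#' @export
default_sponsor_map <- function() {
  c(NIH = "NIH",
    INDUSTRY = "Industry",
    OTHER = "Academic/Other",
    FED = "OtherFederal",
    OTHER_GOV = "OtherFederal",
    NETWORK = "Academic/Other",
    INDIV = "Academic/Other")
}

#' Parse a registry age field into years
#'
#' Registry age limits come as strings such as `"18 Years"`, `"6 Months"`,
#' `"30 Days"`, or the sentinel `"N/A"`. Months divide by 12, weeks by 52,
#' days by 365.25. Unit parsing is case-insensitive.
#'
#' @param text Character vector of age strings.
#' @return Numeric vector of ages in years; `NA` for `"N/A"`, empty, or `NA`
#'   input.
#' @export
#' @examples
#' parse_age_string(c("18 Years", "6 Months", "N/A"))
parse_age_string <- function(text) {
  out <- rep(NA_real_, length(text))
  for (i in seq_along(text)) {
    t <- text[[i]]
    if (is.null(t) || is.na(t)) next
    t <- trimws(as.character(t))
    if (t == "" || toupper(t) == "N/A") next
    m <- regmatches(t, regexec("^([0-9]+(?:\\.[0-9]+)?)[[:space:]]*(years?|months?|weeks?|days?)$",
                               t, ignore.case = TRUE))[[1]]
    if (length(m) == 0L) {
      stop("unparseable age string: '", t, "'", call. = FALSE)
    }
    value <- as.numeric(m[2])
    unit <- tolower(sub("s$", "", m[3]))
    out[i] <- switch(unit,
                     year = value,
                     month = value / 12,
                     week = value / 52,
                     day = value / 365.25)
  }
  out
}

#' Format an age in years as a registry age string
#'
#' Inverse of [parse_age_string()] for whole years.
#'
#' @param years Numeric vector; `NA` becomes `"N/A"`.
#' @return Character vector of registry age strings.
#' @export
format_age_string <- function(years) {
  ifelse(is.na(years), "N/A", paste(format(years, trim = TRUE), "Years"))
}

new_trial_record <- function(trial_id, overall_status, study_type,
                             min_age_years, max_age_years, sex_eligibility,
                             condition_terms, sites, sponsor_class) {
  if (!is.na(min_age_years) && !is.na(max_age_years) &&
      min_age_years > max_age_years) {
    stop("trial ", trial_id, ": min age exceeds max age", call. = FALSE)
  }
  structure(
    list(trial_id = trial_id,
         overall_status = overall_status,
         study_type = study_type,
         min_age_years = min_age_years,
         max_age_years = max_age_years,
         sex_eligibility = sex_eligibility,
         condition_terms = condition_terms,
         sites = sites,
         sponsor_class = sponsor_class),
    class = "trial_record")
}

parse_trial_json <- function(obj, sponsor_map) {
  missing_keys <- setdiff(REGISTRY_REQUIRED_KEYS, names(obj))
  if (length(missing_keys) > 0L) {
    stop("missing required field(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  locs <- obj$Locations %||% list()
  sites <- if (length(locs) == 0L) {
    data.frame(zip3 = character(), country = character(),
               site_status = character(), stringsAsFactors = FALSE)
  } else {
    zips <- vapply(locs, function(l) as.character(l$Zip %||% NA_character_), "")
    countries <- vapply(locs, function(l) as.character(l$Country %||% NA_character_), "")
    statuses <- vapply(locs, function(l) as.character(l$Status %||% NA_character_), "")
    zip3 <- ifelse(is.na(zips), NA_character_, substr(zips, 1L, 3L))
    us <- !is.na(countries) & countries %in% c("United States", "US", "USA")
    bad <- us & !is.na(zip3) & !grepl("^[0-9]{3}$", zip3)
    if (any(bad)) {
      stop("US site with malformed zip: ", paste(zips[bad], collapse = ", "),
           call. = FALSE)
    }
    data.frame(zip3 = zip3, country = countries, site_status = statuses,
               stringsAsFactors = FALSE)
  }
  raw_class <- as.character(obj$LeadSponsorClass)
  sponsor <- sponsor_map[[raw_class]] %||% "Unknown"
  sex <- as.character(obj$Gender)
  if (!sex %in% c("All", "Male", "Female")) {
    stop("unrecognized sex-eligibility value: '", sex, "'", call. = FALSE)
  }
  new_trial_record(
    trial_id = as.character(obj$NCTId),
    overall_status = as.character(obj$OverallStatus),
    study_type = as.character(obj$StudyType),
    min_age_years = parse_age_string(obj$MinimumAge %||% NA_character_),
    max_age_years = parse_age_string(obj$MaximumAge %||% NA_character_),
    sex_eligibility = sex,
    condition_terms = as.character(unlist(obj$Condition)),
    sites = sites,
    sponsor_class = sponsor)
}

#' Read a registry snapshot from JSONL
#'
#' One study record per line, with keys mirroring the public registry API
#' vocabulary (`NCTId`, `OverallStatus`, `StudyType`, `MinimumAge`,
#' `MaximumAge`, `Gender`, `Condition`, `Locations`, `LeadSponsorClass`).
#' Malformed lines are skipped and collected into an error report; record
#' order is preserved.
#'
#' @param path Path to a JSONL file.
#' @param sponsor_map Named character vector mapping raw lead-sponsor classes
#'   to analysis classes; see [default_sponsor_map()].
#' @return List with `records` (list of trial records) and `errors`
#'   (data.frame with `line` and `message`).
#' @export
read_registry <- function(path, sponsor_map = default_sponsor_map()) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  errs <- list()
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch({
      obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
      parse_trial_json(obj, sponsor_map)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(line = i,
                                              message = conditionMessage(rec),
                                              stringsAsFactors = FALSE)
    } else {
      records[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  records <- records[keep]
  ids <- vapply(records, `[[`, "", "trial_id")
  if (anyDuplicated(ids)) {
    stop("duplicate trial_id in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(), message = character(), stringsAsFactors = FALSE)
  list(records = records, errors = errors)
}

#' Write trial records as registry JSONL
#'
#' Inverse of [read_registry()]; used by the registry simulator and for
#' round-trip checks.
#'
#' @param records List of trial records.
#' @param path Output path.
#' @param sponsor_map Mapping used to recover a raw sponsor class label (the
#'   first raw key mapping to the record's class).
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path, sponsor_map = default_sponsor_map()) {
  inv <- names(sponsor_map)[!duplicated(sponsor_map)]
  names(inv) <- sponsor_map[!duplicated(sponsor_map)]
  lines <- vapply(records, function(r) {
    locs <- lapply(seq_len(nrow(r$sites)), function(i) {
      s <- list(Zip = r$sites$zip3[i], Country = r$sites$country[i])
      if (!is.na(r$sites$site_status[i])) s$Status <- r$sites$site_status[i]
      s
    })
    obj <- list(NCTId = r$trial_id,
                OverallStatus = r$overall_status,
                StudyType = r$study_type,
                MinimumAge = format_age_string(r$min_age_years),
                MaximumAge = format_age_string(r$max_age_years),
                Gender = r$sex_eligibility,
                Condition = as.list(r$condition_terms),
                Locations = locs,
                LeadSponsorClass = unname(inv[r$sponsor_class] %||% "OTHER"))
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Sites that count toward US-site and geography checks: US country and either
# no site-level status or status Recruiting.
eligible_us_sites <- function(record) {
  s <- record$sites
  if (nrow(s) == 0L) return(s[0, ])
  us <- !is.na(s$country) & s$country %in% c("United States", "US", "USA")
  ok_status <- is.na(s$site_status) | s$site_status == "Recruiting"
  s[us & ok_status & !is.na(s$zip3), , drop = FALSE]
}

#' Filter a registry to actively recruiting adult interventional US trials
#'
#' Retains records with overall status `Recruiting`, study type
#' `Interventional`, a stated minimum age of at least 18 years, and at least
#' one US site (site-level status, when present, must be `Recruiting`).
#' Output order is preserved and the reference date is attached as an
#' attribute for provenance.
#'
#' @param records List of trial records.
#' @param reference_date Date of the registry snapshot the filter represents.
#' @return Filtered list of trial records with attribute `reference_date`.
#' @export
filter_trials <- function(records, reference_date = Sys.Date()) {
  keep <- vapply(records, function(r) {
    r$overall_status == "Recruiting" &&
      r$study_type == "Interventional" &&
      !is.na(r$min_age_years) && r$min_age_years >= 18 &&
      nrow(eligible_us_sites(r)) > 0L
  }, NA)
  out <- records[keep]
  attr(out, "reference_date") <- as_ref_date(reference_date)
  out
}

#' Fractions of trials with metro and nonmetro sites
#'
#' For a filtered registry, the fraction of trials with at least one eligible
#' US site in a metropolitan zip3 and the fraction with at least one in a
#' nonmetropolitan zip3. The two fractions can sum to more than 1. Site zip3s
#' missing from the lookup count toward neither and are returned for logging.
#'
#' @param records List of (filtered) trial records.
#' @param geo Geography lookup data.frame with columns `zip3`, `metro_flag`
#'   (see [read_geo_lookup()]).
#' @return List with `metro_fraction`, `nonmetro_fraction`, and
#'   `unknown_zip3` (character vector).
#' @export
trial_metro_profile <- function(records, geo) {
  flags <- stats::setNames(geo$metro_flag, geo$zip3)
  unknown <- character()
  any_metro <- any_nonmetro <- logical(length(records))
  for (i in seq_along(records)) {
    zips <- eligible_us_sites(records[[i]])$zip3
    f <- flags[zips]
    unknown <- c(unknown, zips[is.na(f)])
    any_metro[i] <- any(f == "Metropolitan", na.rm = TRUE)
    any_nonmetro[i] <- any(f == "Nonmetropolitan", na.rm = TRUE)
  }
  list(metro_fraction = if (length(records)) mean(any_metro) else NA_real_,
       nonmetro_fraction = if (length(records)) mean(any_nonmetro) else NA_real_,
       unknown_zip3 = unique(unknown))
}
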