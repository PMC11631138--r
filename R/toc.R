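# Trial Opportunities Compass: a 3x3 grid of participant counts x trial
# counts per sponsor class with user-configurable percentile cutoffs.

#' Percentile thresholds for a TOC axis
#'
#' Empirical percentiles with linear interpolation between closest order
#' statistics (quantile type 7).
#'
#' @param values Numeric vector of counts (nonempty).
#' @param p_low,p_high Percentiles in (0, 100), `p_low < p_high`.
#' @return Named numeric vector `c(t_low, t_high)`.
#' @export
#' @examples
#' percentile_thresholds(1:10, 20, 80)
percentile_thresholds <- function(values, p_low = 20, p_high = 80) {
  if (length(values) == 0L) stop("empty values", call. = FALSE)
  if (!(p_low > 0 && p_high < 100 && p_low < p_high)) {
    stop("need 0 < p_low < p_high < 100", call. = FALSE)
  }
  q <- stats::quantile(values, c(p_low, p_high) / 100, type = 7, names = FALSE)
  c(t_low = q[1], t_high = q[2])
}

classify_axis <- function(value, thresholds) {
  ifelse(value < thresholds[["t_low"]], "Few",
         ifelse(value > thresholds[["t_high"]], "Many", "Some"))
}

#' Classify a condition into a TOC region
#'
#' Per axis: `Few` strictly below the low threshold, `Many` strictly above
#' the high threshold, otherwise `Some` — ties at a threshold fall inward to
#' `Some`. The region label pairs the participant axis with the trial axis.
#'
#' @param participant_count,trial_count Numeric values.
#' @param participant_thresholds,trial_thresholds Outputs of
#'   [percentile_thresholds()].
#' @return Character region label, e.g. `"Many participants / Few trials"`.
#' @export
classify_region <- function(participant_count, trial_count,
                            participant_thresholds, trial_thresholds) {
  paste0(classify_axis(participant_count, participant_thresholds),
         " participants / ",
         classify_axis(trial_count, trial_thresholds), " trials")
}

#' Build the Trial Opportunities Compass table
#'
#' For the `top_k` most common conditions (by participant count): the number
#' of participants with the phecode present, and per sponsor class the number
#' of filtered trials linked to the phecode, with the 3x3 region label.
#' Trial counts use condition linkage only (no per-participant age/sex/geo
#' restriction) unless `restrict_to_matched` supplies a match audit, in which
#' case only trials matched to at least one participant count. Participant
#' thresholds are computed once across the top-k conditions; trial thresholds
#' per sponsor class.
#'
#' @param profiles Condition profiles data.table.
#' @param registry Filtered trial records.
#' @param linkage A `condition_linkage`.
#' @param map A `phecode_map` (condition names).
#' @param p_low,p_high Percentile cutoffs (default 20/80).
#' @param top_k Number of most common conditions to include (default 20).
#' @param restrict_to_matched Optional audit table from [match_cohort()];
#'   when given, a trial counts toward a (phecode, sponsor) cell only if it
#'   matched at least one participant.
#' @return List with `table` (data.frame: `phecode`, `condition`,
#'   `sponsor_class`, `participant_count`, `trial_count`, `region`) and
#'   `thresholds` (participant axis and per-sponsor trial axis).
#' @export
build_toc <- function(profiles, registry, linkage, map,
                      p_low = 20, p_high = 80, top_k = 20,
                      restrict_to_matched = NULL) {
  pr <- data.table::as.data.table(profiles)[present == TRUE]
  pcounts <- pr[, .(participant_count = data.table::uniqueN(participant_id)),
                by = phecode][order(-participant_count, phecode)]
  top <- utils::head(pcounts, top_k)
  sponsors <- sort(unique(vapply(registry, `[[`, "", "sponsor_class")))

  matched_ids <- if (!is.null(restrict_to_matched)) unique(restrict_to_matched$trial_id)
  tcounts <- data.table::rbindlist(lapply(registry, function(tr) {
    if (!is.null(matched_ids) && !tr$trial_id %in% matched_ids) return(NULL)
    linked <- intersect(link_conditions(tr, linkage), top$phecode)
    if (length(linked) == 0L) return(NULL)
    data.table::data.table(phecode = linked, sponsor_class = tr$sponsor_class)
  }))
  grid <- data.table::CJ(phecode = top$phecode, sponsor_class = sponsors)
  if (nrow(tcounts) > 0L) {
    tc <- tcounts[, .(trial_count = .N), by = .(phecode, sponsor_class)]
    grid <- tc[grid, on = c("phecode", "sponsor_class")]
  } else {
    grid[, trial_count := 0L]
  }
  grid[is.na(trial_count), trial_count := 0L]
  grid <- top[grid, on = "phecode"]

  pth <- percentile_thresholds(top$participant_count, p_low, p_high)
  tth <- lapply(stats::setNames(sponsors, sponsors), function(s) {
    percentile_thresholds(grid$trial_count[grid$sponsor_class == s], p_low, p_high)
  })
  grid[, region := mapply(function(pc, tc, s) classify_region(pc, tc, pth, tth[[s]]),
                          participant_count, trial_count, sponsor_class)]
  grid[, condition := unname(map$phecodes[phecode])]
  data.table::setcolorder(grid, c("phecode", "condition", "sponsor_class",
                                  "participant_count", "trial_count", "region"))
  list(table = as.data.frame(grid[order(sponsor_class, -participant_count, phecode)]),
       thresholds = list(participants = pth, trials = tth))
}
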