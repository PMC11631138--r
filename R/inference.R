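# Negative-binomial regression engine (NB2, log link, ML dispersion) and the
# two analyses built on it: the phenome-wide scan of matched-trial counts and
# the SDoH adjusted-ratio analysis.

#' Fit a negative-binomial regression (NB2, log link)
#'
#' Maximum-likelihood fit of a negative-binomial model with variance
#' `mu + alpha * mu^2`; the dispersion `alpha` is estimated jointly by ML.
#' Collinear terms are dropped with a warning. Data at the Poisson boundary
#' (no overdispersion) are handled by refitting as Poisson with `alpha = 0`.
#' Non-convergence yields a fit with `converged = FALSE`, not an error.
#'
#' @param design Data.frame of named covariates (numeric, character, or
#'   factor columns).
#' @param counts Non-negative integer outcome vector.
#' @return An `nb_fit`: list with `term_names`, `coefficients`, `se`,
#'   `alpha` (dispersion), `theta` (`1/alpha`), `loglik`, `converged`,
#'   `n`, `dispersion_boundary`, `dropped_terms`.
#' @export
fit_negative_binomial <- function(design, counts) {
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  design <- as.data.frame(design)
  if (nrow(design) != length(counts)) {
    stop("design and counts lengths differ", call. = FALSE)
  }
  # drop covariates with a single observed level (no contrast possible)
  single <- vapply(design, function(x) length(unique(x[!is.na(x)])) < 2L, NA)
  if (any(single)) {
    warning("dropping single-level covariate(s): ",
            paste(names(design)[single], collapse = ", "), call. = FALSE)
    design <- design[, !single, drop = FALSE]
  }
  dat <- cbind(.y = as.integer(round(counts)), design)
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)

  boundary <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(.y ~ ., data = dat, control = ctrl),
      warning = function(w) {
        # theta walking to infinity signals the Poisson boundary
        if (grepl("iteration limit|alternation", conditionMessage(w))) {
          boundary <<- TRUE
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)

  theta_huge <- !inherits(fit, "error") && isTRUE(fit$theta > 1e6)
  if (inherits(fit, "error") || theta_huge || boundary) {
    # Poisson boundary of the NB family: alpha = 0
    pfit <- tryCatch(stats::glm(.y ~ ., data = dat, family = stats::poisson(),
                                control = ctrl),
                     error = function(e) e)
    if (inherits(pfit, "error")) {
      return(structure(list(term_names = character(), coefficients = numeric(),
                            se = numeric(), alpha = NA_real_, theta = NA_real_,
                            loglik = NA_real_, converged = FALSE,
                            n = nrow(dat), dispersion_boundary = NA,
                            dropped_terms = character(),
                            reason = conditionMessage(if (inherits(fit, "error")) fit else pfit)),
                       class = "nb_fit"))
    }
    fit <- pfit
    alpha <- 0
    theta <- Inf
    boundary <- TRUE
  } else {
    theta <- fit$theta
    alpha <- 1 / theta
  }

  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    warning("dropping collinear term(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  keep <- !is.na(cf)
  se <- rep(NA_real_, sum(keep))
  sm <- summary(fit)$coefficients
  se <- sm[match(names(cf)[keep], rownames(sm)), "Std. Error"]
  structure(list(term_names = names(cf)[keep],
                 coefficients = unname(cf[keep]),
                 se = unname(se),
                 alpha = alpha,
                 theta = theta,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = isTRUE(fit$converged),
                 n = nrow(dat),
                 dispersion_boundary = boundary,
                 dropped_terms = dropped),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial fit (NB2, log link)\n")
  cat(sprintf("  n = %d, dispersion alpha = %.4g, logLik = %.2f, converged: %s\n",
              x$n, x$alpha, x$loglik, x$converged))
  print(data.frame(term = x$term_names, coef = x$coefficients, se = x$se))
  invisible(x)
}

#' Count-ratio summary for one model term
#'
#' Exponentiated coefficient (count ratio), percent change, Wald 95% CI, and
#' two-sided Wald p-value. P-values below the double-precision floor are
#' reported as the bound `1e-300` with `p_underflow = TRUE`; the exact
#' magnitude is carried in `neglog10_p`.
#'
#' @param fit An `nb_fit`.
#' @param term Term name (as in `fit$term_names`).
#' @return List: `term`, `ratio`, `percent_change`, `ci_low`, `ci_high`,
#'   `p`, `p_underflow`, `neglog10_p`.
#' @export
coefficient_summary <- function(fit, term) {
  idx <- match(term, fit$term_names)
  if (is.na(idx)) stop("unknown term: ", term, call. = FALSE)
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; no summary reported", call. = FALSE)
  }
  b <- fit$coefficients[idx]
  se <- fit$se[idx]
  z <- b / se
  log_p <- log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  neglog10 <- -log_p / log(10)
  underflow <- neglog10 > 300
  p <- if (underflow) 1e-300 else exp(log_p)
  list(term = term,
       ratio = exp(b),
       percent_change = (exp(b) - 1) * 100,
       ci_low = exp(b - 1.96 * se),
       ci_high = exp(b + 1.96 * se),
       p = p,
       p_underflow = underflow,
       neglog10_p = neglog10)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of tests (at least 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

PHEWAS_COVARIATES <- c("age_years", "sex_at_birth", "metro", "race_ethnicity",
                       "education", "low_income", "disability", "n_conditions")

#' Phenome-wide scan of matched-trial counts
#'
#' One negative-binomial regression per phecode: matched-trial count as the
#' outcome, the phecode's presence indicator as the term of interest, and a
#' fixed adjustment set (by default age, sex at birth, metro location,
#' race/ethnicity, education, low income, disability, and number of
#' conditions). Participants with missing adjustment covariates are excluded
#' listwise; phecodes with fewer than `min_cases` cases among included
#' participants are skipped. The Bonferroni threshold uses the number of
#' phecodes actually tested.
#'
#' @param covariates Covariate table from [derive_covariates()].
#' @param profiles Condition profiles data.table.
#' @param counts Count table from [match_cohort()] (or any table with
#'   `participant_id` and `total_matches`).
#' @param map A `phecode_map` (condition names and domains).
#' @param min_cases Minimum cases per tested phecode (default 20).
#' @param alpha Family-wise level (default 0.05).
#' @param covariate_terms Adjustment covariate names (columns of
#'   `covariates`).
#' @param phecodes Optional subset of phecodes to test (default: all with a
#'   present case).
#' @return List: `results` (data.frame sorted by p), `m`, `threshold`,
#'   `n_included`, `skipped` (data.frame with reasons).
#' @export
run_phewas <- function(covariates, profiles, counts, map,
                       min_cases = 20L, alpha = 0.05,
                       covariate_terms = PHEWAS_COVARIATES,
                       phecodes = NULL) {
  cv <- data.table::as.data.table(covariates)
  dt <- merge(cv, data.table::as.data.table(counts)[, .(participant_id, total_matches)],
              by = "participant_id")
  need <- c("total_matches", covariate_terms)
  complete <- stats::complete.cases(dt[, need, with = FALSE])
  dt <- dt[complete]
  base <- as.data.frame(dt[, covariate_terms, with = FALSE])
  outcome <- dt$total_matches
  ids <- dt$participant_id

  pr <- data.table::as.data.table(profiles)[present == TRUE & participant_id %in% ids]
  cases_by_phecode <- split(pr$participant_id, pr$phecode)
  test_set <- phecodes %||% names(cases_by_phecode)

  rows <- list()
  skipped <- list()
  for (ph in test_set) {
    case_ids <- cases_by_phecode[[ph]] %||% character()
    n_cases <- length(unique(case_ids))
    if (n_cases < min_cases) {
      skipped[[ph]] <- data.frame(phecode = ph, n_cases = n_cases,
                                  reason = "below min_cases")
      next
    }
    des <- cbind(.presence = as.integer(ids %in% case_ids), base)
    fit <- suppressWarnings(fit_negative_binomial(des, outcome))
    if (!isTRUE(fit$converged) || !".presence" %in% fit$term_names) {
      skipped[[ph]] <- data.frame(phecode = ph, n_cases = n_cases,
                                  reason = fit$reason %||% "did not converge")
      next
    }
    s <- coefficient_summary(fit, ".presence")
    rows[[ph]] <- data.frame(
      phecode = ph,
      condition = unname(map$phecodes[ph]) %||% NA_character_,
      domain = unname(map$domains[ph]) %||% NA_character_,
      n_cases = n_cases,
      ratio = s$ratio, ci_low = s$ci_low, ci_high = s$ci_high,
      percent_change = s$percent_change,
      p = s$p, p_underflow = s$p_underflow, neglog10_p = s$neglog10_p,
      stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phecode = character(), condition = character(),
               domain = character(), n_cases = integer(), ratio = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               percent_change = numeric(), p = numeric(),
               p_underflow = logical(), neglog10_p = numeric())
  m <- nrow(results)
  threshold <- if (m > 0) bonferroni_threshold(alpha, m) else NA_real_
  if (m > 0) {
    results$significant <- results$p < threshold
    results <- results[order(-results$neglog10_p), ]
    rownames(results) <- NULL
  }
  list(results = results, m = m, threshold = threshold,
       n_included = length(ids),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(phecode = character(), n_cases = integer(),
                    reason = character()))
}

SDOH_COVARIATES <- c("age_years", "sex_at_birth", "race_ethnicity", "metro",
                     "low_income", "education", "english_proficient",
                     "food_insecurity", "discrimination_score",
                     "social_support_score", "housing_quality",
                     "neighborhood_cohesion_score", "n_conditions")

SDOH_REFERENCE_LEVELS <- list(
  race_ethnicity = "White",
  sex_at_birth = "Female",
  metro = "Metropolitan",
  housing_quality = "Good",
  low_income = "No",
  food_insecurity = "No",
  education = "11orBelow",
  english_proficient = "No")

relevel_with_reference <- function(x, ref) {
  f <- factor(x)
  if (ref %in% levels(f)) stats::relevel(f, ref = ref) else f
}

#' Adjusted analysis of social determinants of health
#'
#' One multivariable negative-binomial regression per outcome (total matched
#' trials and each consolidated condition domain), with demographic, SDoH,
#' and condition-count covariates. Categorical covariates use fixed
#' reference levels (White, Female, Metropolitan, Good housing, not low
#' income, no food insecurity, education 11 or below, not English
#' proficient); reference rows appear with ratio 1 and no interval.
#' Significance is Bonferroni-controlled across all non-reference
#' coefficients tested over all outcomes.
#'
#' @param covariates Covariate table including SDoH columns.
#' @param counts Count table from [match_cohort()].
#' @param alpha Family-wise level (default 0.05).
#' @param covariate_terms Covariate names (default [`SDOH_COVARIATES`]).
#' @param outcomes Outcome columns; default `total_matches` plus every
#'   `domain_*` column present.
#' @return List: `results` (data.frame: `outcome`, `covariate`, `level`,
#'   `reference`, `ratio`, `ci_low`, `ci_high`, `p`, `p_underflow`,
#'   `significant`), `threshold`, `m`, `n_included` (named by outcome).
#' @export
run_sdoh <- function(covariates, counts, alpha = 0.05,
                     covariate_terms = SDOH_COVARIATES, outcomes = NULL) {
  cv <- data.table::as.data.table(covariates)
  ct <- data.table::as.data.table(counts)
  outcomes <- outcomes %||% intersect(c("total_matches", grep("^domain_", names(ct), value = TRUE)),
                                      names(ct))
  dt <- merge(cv, ct, by = "participant_id")
  covariate_terms <- intersect(covariate_terms, names(dt))
  complete <- stats::complete.cases(dt[, covariate_terms, with = FALSE])
  dt <- dt[complete]

  base <- as.data.frame(dt[, covariate_terms, with = FALSE])
  for (v in names(SDOH_REFERENCE_LEVELS)) {
    if (v %in% names(base)) {
      base[[v]] <- relevel_with_reference(base[[v]], SDOH_REFERENCE_LEVELS[[v]])
    }
  }

  all_rows <- list()
  n_included <- stats::setNames(integer(length(outcomes)), outcomes)
  for (out in outcomes) {
    y <- dt[[out]]
    n_included[out] <- length(y)
    fit <- suppressWarnings(fit_negative_binomial(base, y))
    if (!isTRUE(fit$converged)) next
    label <- if (out == "total_matches") "Total" else sub("^domain_", "", out)
    for (v in covariate_terms) {
      x <- base[[v]]
      if (is.factor(x) || is.character(x)) {
        f <- factor(x)
        ref <- levels(f)[1]
        all_rows[[length(all_rows) + 1L]] <- data.frame(
          outcome = label, covariate = v, level = ref, reference = TRUE,
          ratio = 1, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
          p_underflow = FALSE, stringsAsFactors = FALSE)
        for (lev in levels(f)[-1]) {
          tn <- paste0(v, lev)
          if (!tn %in% fit$term_names) next
          s <- coefficient_summary(fit, tn)
          all_rows[[length(all_rows) + 1L]] <- data.frame(
            outcome = label, covariate = v, level = lev, reference = FALSE,
            ratio = s$ratio, ci_low = s$ci_low, ci_high = s$ci_high,
            p = s$p, p_underflow = s$p_underflow, stringsAsFactors = FALSE)
        }
      } else {
        if (!v %in% fit$term_names) next
        s <- coefficient_summary(fit, v)
        all_rows[[length(all_rows) + 1L]] <- data.frame(
          outcome = label, covariate = v, level = "(per unit)",
          reference = FALSE, ratio = s$ratio, ci_low = s$ci_low,
          ci_high = s$ci_high, p = s$p, p_underflow = s$p_underflow,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, all_rows)
  m <- sum(!results$reference)
  threshold <- if (m > 0) bonferroni_threshold(alpha, m) else NA_real_
  results$significant <- !results$reference & !is.na(results$p) &
    results$p < threshold
  rownames(results) <- NULL
  list(results = results, threshold = threshold, m = m,
       n_included = n_included)
}

#' Plot-ready Manhattan table for the phenome-wide scan
#'
#' One row per tested phecode with `-log10(p)` capped at 300 (underflowed
#' p-values sit at the cap with their flag), the Bonferroni threshold line,
#' and a label flag for the `top_k` most significant conditions.
#'
#' @param phewas Output of [run_phewas()].
#' @param top_k Number of most significant conditions to flag for labeling
#'   (default 20).
#' @return data.frame: `phecode`, `condition`, `domain`, `neglog10_p`,
#'   `p_underflow`, `threshold_line`, `label`.
#' @export
manhattan_export <- function(phewas, top_k = 20L) {
  res <- phewas$results
  if (nrow(res) == 0L) stop("no scan results to export", call. = FALSE)
  ord <- order(-res$neglog10_p)
  label <- logical(nrow(res))
  label[ord[seq_len(min(top_k, nrow(res)))]] <- TRUE
  data.frame(phecode = res$phecode,
             condition = res$condition,
             domain = res$domain,
             neglog10_p = pmin(res$neglog10_p, 300),
             p_underflow = res$neglog10_p > 300 | res$p_underflow,
             threshold_line = -log10(phewas$threshold),
             label = label,
             stringsAsFactors = FALSE)
}
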