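# Pipeline orchestration: one config, named stages, CSV/JSONL products, and
# a run manifest with input checksums for provenance.

#' Build a validated run configuration
#'
#' A flat list of paths and analysis settings shared by every pipeline
#' stage. Input paths are checked at run time, not here, because the
#' `simulate` stage creates them.
#'
#' @param outdir Output directory for stage products and the manifest.
#' @param registry,cohort,events,phecode_map,geo,income_limits Input paths;
#'   defaults point inside `outdir` where the `simulate` stage writes them.
#' @param reference_date Reference date for age evaluation and filter
#'   provenance.
#' @param min_instances Presence rule (default 2).
#' @param min_cases Case floor for the phenome-wide scan (default 20).
#' @param p_low,p_high,top_k TOC percentile cutoffs and condition count.
#' @param alpha Family-wise significance level in (0, 1).
#' @param seed Integer seed for the simulate stage.
#' @param n_participants,n_trials Simulate-stage sizes.
#' @param distinct_dates Rule-of-two counts distinct dates (default) or raw
#'   rows.
#' @param toc_restrict_to_matched Restrict TOC trial counts to trials
#'   matched to at least one participant.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir,
                       registry = file.path(outdir, "registry.jsonl"),
                       cohort = file.path(outdir, "cohort.csv"),
                       events = file.path(outdir, "icd_events.csv"),
                       phecode_map = system.file("extdata", "phecode_map_synthetic.csv",
                                                package = "trialopps"),
                       geo = file.path(outdir, "zip3_metro.csv"),
                       income_limits = file.path(outdir, "income_limits.csv"),
                       reference_date = as.Date("2023-02-14"),
                       min_instances = 2L,
                       min_cases = 20L,
                       p_low = 20, p_high = 80, top_k = 20L,
                       alpha = 0.05,
                       seed = 1L,
                       n_participants = 500L,
                       n_trials = 300L,
                       distinct_dates = TRUE,
                       toc_restrict_to_matched = FALSE) {
  problems <- character()
  if (!(alpha > 0 && alpha < 1)) problems <- c(problems, "alpha must be in (0, 1)")
  if (!(p_low > 0 && p_low < p_high && p_high < 100)) {
    problems <- c(problems, "need 0 < p_low < p_high < 100")
  }
  if (min_instances < 1) problems <- c(problems, "min_instances must be at least 1")
  if (length(problems)) {
    stop("invalid config: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  structure(as.list(environment())[setdiff(ls(), "problems")],
            class = "run_config")
}

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

PIPELINE_STAGES <- c("simulate", "phenotype", "match", "toc", "phewas",
                     "sdoh", "report")

stage_requires <- list(
  phenotype = character(),
  match = "phenotype",
  toc = "phenotype",
  phewas = "match",
  sdoh = "match",
  report = "match")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (demo cohort +
#' registry), `phenotype` (condition profiles + covariates), `match`
#' (matched-trial counts), `toc`, `phewas`, `sdoh`, and `report`
#' (stratified means and the cohort summary). Each stage writes its products
#' under `config$outdir`; a manifest records the config, input checksums,
#' seed, and row counts. Rerunning with identical config and inputs
#' reproduces identical products.
#'
#' @param config A `run_config`.
#' @param stages Subset of [`PIPELINE_STAGES`] (default: all).
#' @return Invisibly, a list with the in-memory stage products and the
#'   manifest.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  products <- list()
  log_line <- function(stage, msg) message(sprintf("[%s] %s", stage, msg))

  input_paths <- c(registry = cfg$registry, cohort = cfg$cohort,
                   events = cfg$events, phecode_map = cfg$phecode_map,
                   geo = cfg$geo, income_limits = cfg$income_limits)

  # a required stage is satisfied by in-memory state from this invocation or,
  # failing that, by its products already on disk from an earlier run
  hydrate <- function(stage) {
    if (stage == "phenotype") {
      pfile <- file.path(cfg$outdir, "condition_profiles.csv")
      cfile <- file.path(cfg$outdir, "covariates.csv")
      if (!file.exists(pfile) || !file.exists(cfile)) return(NULL)
      inputs <- load_inputs()
      profiles <- data.table::fread(pfile, colClasses = list(
        character = c("participant_id", "phecode")))
      covariates <- data.table::fread(cfile, colClasses = list(
        character = c("participant_id", "zip3")), na.strings = c("", "NA"))
      list(profiles = profiles, covariates = covariates,
           coverage = NULL, inputs = inputs)
    } else if (stage == "match") {
      mfile <- file.path(cfg$outdir, "match_counts.csv")
      afile <- file.path(cfg$outdir, "match_audit.csv")
      if (!file.exists(mfile) || !file.exists(afile)) return(NULL)
      ph <- state$phenotype
      filtered <- filter_trials(ph$inputs$registry, cfg$reference_date)
      list(counts = data.table::fread(mfile, colClasses = list(character = "participant_id")),
           audit = data.table::fread(afile, colClasses = "character"),
           filtered = filtered,
           linkage = build_condition_linkage(ph$inputs$map))
    }
  }

  require_stage <- function(stage) {
    for (need in stage_requires[[stage]] %||% character()) {
      if (need %in% names(state)) next
      if (need %in% names(stage_requires)) require_stage(need)
      loaded <- tryCatch(hydrate(need), error = function(e) NULL)
      if (is.null(loaded)) {
        stop(sprintf("stage '%s' requires prior stage '%s'; run it first",
                     stage, need), call. = FALSE)
      }
      state[[need]] <<- loaded
    }
  }

  map <- NULL
  load_inputs <- function() {
    missing <- input_paths[!file.exists(input_paths)]
    if (length(missing)) {
      stop("missing input file(s): ", paste(missing, collapse = ", "),
           "; run the simulate stage or point the config at existing files",
           call. = FALSE)
    }
    list(map = read_phecode_map(cfg$phecode_map),
         cohort = read_cohort(cfg$cohort),
         events = read_icd_events(cfg$events),
         geo = read_geo_lookup(cfg$geo),
         limits = read_income_limits(cfg$income_limits),
         registry = read_registry(cfg$registry)$records)
  }

  for (stage in stages) {
    if (stage == "simulate") {
      map <- read_phecode_map(cfg$phecode_map)
      sim <- simulate_cohort(cohort_sim_params(n = cfg$n_participants, map = map,
                                               seed = cfg$seed),
                             dir = cfg$outdir)
      simulate_registry(registry_sim_params(n = cfg$n_trials, map = map,
                                            seed = cfg$seed),
                        path = cfg$registry)
      log_line(stage, sprintf("%d participants, %d events, %d trials",
                              nrow(sim$cohort), nrow(sim$events), cfg$n_trials))
      products$simulate <- TRUE
    } else if (stage == "phenotype") {
      inputs <- load_inputs()
      prof <- build_condition_profiles(inputs$events, inputs$map,
                                       min_instances = cfg$min_instances,
                                       distinct_dates = cfg$distinct_dates)
      cov <- derive_covariates(inputs$cohort, prof$profiles, inputs$geo,
                               inputs$limits, reference_date = cfg$reference_date)
      data.table::fwrite(prof$profiles, file.path(cfg$outdir, "condition_profiles.csv"))
      data.table::fwrite(cov, file.path(cfg$outdir, "covariates.csv"))
      state$phenotype <- list(profiles = prof$profiles, covariates = cov,
                              coverage = prof$coverage, inputs = inputs)
      log_line(stage, sprintf("%d profile rows, map coverage %.3f",
                              nrow(prof$profiles), prof$coverage$mapped_fraction))
    } else if (stage == "match") {
      require_stage("match")
      ph <- state$phenotype
      filtered <- filter_trials(ph$inputs$registry, cfg$reference_date)
      linkage <- build_condition_linkage(ph$inputs$map)
      mr <- match_cohort(ph$covariates, ph$profiles, filtered, linkage)
      data.table::fwrite(mr$counts, file.path(cfg$outdir, "match_counts.csv"))
      data.table::fwrite(mr$audit, file.path(cfg$outdir, "match_audit.csv"))
      state$match <- list(counts = mr$counts, audit = mr$audit,
                          filtered = filtered, linkage = linkage)
      log_line(stage, sprintf("%d/%d trials pass filters; mean matched = %.2f",
                              length(filtered), length(ph$inputs$registry),
                              mean(mr$counts$total_matches)))
    } else if (stage == "toc") {
      require_stage("toc")
      ph <- state$phenotype
      filtered <- state$match$filtered %||%
        filter_trials(ph$inputs$registry, cfg$reference_date)
      linkage <- state$match$linkage %||% build_condition_linkage(ph$inputs$map)
      toc <- build_toc(ph$profiles, filtered, linkage, ph$inputs$map,
                       p_low = cfg$p_low, p_high = cfg$p_high, top_k = cfg$top_k,
                       restrict_to_matched = if (cfg$toc_restrict_to_matched)
                         state$match$audit)
      utils::write.csv(toc$table, file.path(cfg$outdir, "toc.csv"), row.names = FALSE)
      state$toc <- toc
      log_line(stage, sprintf("%d cells", nrow(toc$table)))
    } else if (stage == "phewas") {
      require_stage("phewas")
      ph <- state$phenotype
      pw <- run_phewas(ph$covariates, ph$profiles, state$match$counts,
                       ph$inputs$map, min_cases = cfg$min_cases, alpha = cfg$alpha)
      utils::write.csv(pw$results, file.path(cfg$outdir, "phewas.csv"), row.names = FALSE)
      if (nrow(pw$results) > 0) {
        utils::write.csv(manhattan_export(pw),
                         file.path(cfg$outdir, "manhattan.csv"), row.names = FALSE)
      }
      state$phewas <- pw
      log_line(stage, sprintf("%d phecodes tested, threshold %.3g, %d significant",
                              pw$m, pw$threshold, sum(pw$results$significant)))
    } else if (stage == "sdoh") {
      require_stage("sdoh")
      ph <- state$phenotype
      sd <- run_sdoh(ph$covariates, state$match$counts, alpha = cfg$alpha)
      utils::write.csv(sd$results, file.path(cfg$outdir, "sdoh.csv"), row.names = FALSE)
      state$sdoh <- sd
      log_line(stage, sprintf("%d coefficients tested, %d significant",
                              sd$m, sum(sd$results$significant, na.rm = TRUE)))
    } else if (stage == "report") {
      require_stage("report")
      ph <- state$phenotype
      summ <- cohort_summary(ph$covariates, ph$profiles, ph$inputs$map)
      utils::write.csv(summ, file.path(cfg$outdir, "cohort_summary.csv"), row.names = FALSE)
      strata <- do.call(rbind, lapply(
        c("metro", "sex_at_birth", "race_ethnicity", "age_group", "education",
          "low_income", "disability"),
        function(s) cbind(stratifier = s,
                          stratified_mean_matches(state$match$counts,
                                                  ph$covariates, s))))
      utils::write.csv(strata, file.path(cfg$outdir, "stratified_means.csv"),
                       row.names = FALSE)
      state$report <- list(summary = summ, strata = strata)
      log_line(stage, "cohort summary and stratified means written")
    }
  }

  product_files <- list.files(cfg$outdir, pattern = "\\.(csv|jsonl)$",
                              full.names = TRUE)
  manifest <- list(
    config = cfg[setdiff(names(cfg), "outdir")],
    stages = stages,
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    input_checksums = checksum_files(input_paths),
    products = lapply(stats::setNames(product_files, basename(product_files)),
                      function(f) {
                        n_lines <- length(readLines(f, warn = FALSE))
                        list(md5 = unname(tools::md5sum(f)),
                             rows = if (grepl("\\.csv$", f)) n_lines - 1L else n_lines)
                      }))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
  invisible(list(state = state, manifest = manifest))
}
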