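#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' before any computation starts.
#'
#' @param seed Single pipeline seed, fanned out deterministically to every
#'   stochastic stage (simulation, fold assignment, bootstraps,
#'   permutations).
#' @param generator A [cohort_config()]; its own seed is overridden by
#'   `seed`. Ignored when `paths` supplies real logs.
#' @param paths Optional list `sessions`, `daily` of CSV paths to ingest
#'   instead of simulating.
#' @param n_lags Lags for Markov unfolding (default 7).
#' @param correlation_threshold Absolute-correlation pruning cutoff
#'   (default 0.85).
#' @param outcomes Outcomes to model.
#' @param group_learner Learner for the group models (default lasso, the
#'   best performer among the suite for this problem family).
#' @param individual_learners Learners considered per athlete.
#' @param adjust Pairwise adjustment for the model-family comparison:
#'   `"sidak"` or `"tukey"`.
#' @param same_day Same-day availability policy, see [build_model_data()].
#' @param bootstrap_B Bootstrap resamples for individual metrics.
#' @param cv_repeats,cv_folds Repeated-CV geometry for individual model
#'   selection.
#' @param min_rows Minimum usable rows per athlete for individual models.
#' @return List of class `wc_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = cohort_config(),
                            paths = NULL,
                            n_lags = 7,
                            correlation_threshold = 0.85,
                            outcomes = c("am_prs", "hrv_change"),
                            group_learner = "lasso",
                            individual_learners = "lasso",
                            adjust = "sidak",
                            same_day = "morning_only",
                            bootstrap_B = 500,
                            cv_repeats = 10,
                            cv_folds = 10,
                            min_rows = 30) {
  cfg <- list(seed = as.integer(seed), generator = generator, paths = paths,
              n_lags = n_lags, correlation_threshold = correlation_threshold,
              outcomes = outcomes, group_learner = group_learner,
              individual_learners = individual_learners, adjust = adjust,
              same_day = same_day, bootstrap_B = bootstrap_B,
              cv_repeats = cv_repeats, cv_folds = cv_folds,
              min_rows = min_rows)
  if (!inherits(generator, "wc_cohort_config") && is.null(paths))
    stop_config("generator", "must be a cohort_config() when no paths are given")
  if (!all(outcomes %in% c("am_prs", "hrv_change")))
    stop_config("outcomes", "must be among am_prs, hrv_change")
  if (!adjust %in% c("sidak", "tukey"))
    stop_config("adjust", "must be sidak or tukey")
  if (!same_day %in% c("morning_only", "all"))
    stop_config("same_day", "must be morning_only or all")
  if (n_lags < 0) stop_config("n_lags", "must be >= 0")
  structure(cfg, class = "wc_pipeline_config")
}

#' Validate and ingest raw log CSVs
#'
#' Reads the two log tables, types their columns, and range-checks every
#' row; violations are reported with row numbers. The schema is the same
#' one the simulator writes, so synthetic output round-trips unchanged.
#'
#' @param sessions_path,daily_path CSV paths.
#' @return List `sessions`, `daily` of validated tibbles.
#' @export
ingest_logs <- function(sessions_path, daily_path) {
  for (p in c(sessions_path, daily_path)) {
    if (!file.exists(p)) stop_validation(paste("file not found:", p))
  }
  sessions <- as_tibble(read.csv(sessions_path, stringsAsFactors = FALSE))
  daily <- as_tibble(read.csv(daily_path, stringsAsFactors = FALSE))
  sessions$date <- as.Date(sessions$date)
  daily$date <- as.Date(daily$date)

  need_s <- c("participant_id", "date", "modality", "duration_min", "rpe",
              "pre_ex_cho_g")
  need_d <- c("participant_id", "date", "kcal_per_kg", "cho_g_per_kg",
              "fat_g_per_kg", "protein_g_per_kg", "sleep_h", "sleep_quality",
              "soreness", "life_stress", "am_prs", "ln_rmssd", "resting_hr",
              "body_mass_kg")
  ms <- setdiff(need_s, names(sessions)); md <- setdiff(need_d, names(daily))
  if (length(ms)) stop_validation(paste("sessions missing columns:", paste(ms, collapse = ", ")))
  if (length(md)) stop_validation(paste("daily missing columns:", paste(md, collapse = ", ")))

  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- c(
    if (length(r <- bad(sessions$rpe < 0 | sessions$rpe > 100)))
      sprintf("sessions row %d: rpe outside [0, 100]", r),
    if (length(r <- bad(sessions$duration_min <= 0)))
      sprintf("sessions row %d: duration_min must be > 0", r),
    if (length(r <- bad(daily$sleep_quality < 1 | daily$sleep_quality > 7)))
      sprintf("daily row %d: sleep_quality outside [1, 7]", r),
    if (length(r <- bad(daily$soreness < 1 | daily$soreness > 10)))
      sprintf("daily row %d: soreness outside [1, 10]", r),
    if (length(r <- bad(daily$life_stress < 1 | daily$life_stress > 7)))
      sprintf("daily row %d: life_stress outside [1, 7]", r),
    if (length(r <- bad(daily$am_prs < 0 | daily$am_prs > 100)))
      sprintf("daily row %d: am_prs outside [0, 100]", r)
  )
  dup <- which(duplicated(daily[c("participant_id", "date")]))
  if (length(dup)) problems <- c(problems,
    sprintf("daily row %d: duplicate participant-day", dup))
  if (length(problems))
    stop_validation(paste0("log validation failed:\n  ",
                           paste(head(problems, 20), collapse = "\n  ")))
  list(sessions = sessions, daily = daily)
}

#' Write a simulated cohort to disk
#'
#' Sessions and daily logs as UTF-8 CSV with ISO-8601 dates, the ground
#' truth (athlete profiles, effect sizes, true drivers) as JSON beside
#' them.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- file.path(dir, c("sessions.csv", "daily.csv", "ground_truth.json"))
  write.csv(cohort$sessions, ps[1], row.names = FALSE)
  write.csv(cohort$daily, ps[2], row.names = FALSE)
  jsonlite::write_json(list(
    profiles = cohort$truth$profiles,
    effect_sizes = cohort$truth$effect_sizes,
    true_drivers = cohort$truth$true_drivers
  ), ps[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ps)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end: simulate (or ingest) the cohort,
#' apply inclusion rules, impute, engineer features, Markov-unfold, fit the
#' group models (baseline, full-set learner, top-five mixed model) for each
#' outcome, fit the individualized models (best learner per athlete, the
#' two top-five linear models and the per-athlete baseline), compute
#' importance and partial-dependence products, compare the individual model
#' families with a mixed model, and write the report bundle. Each stage
#' logs row/column counts; the run is reproducible from `(config, seed)`
#' and a manifest of artifact hashes is written.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory to create and fill.
#' @return Invisibly, a list with the fitted objects (`fits`,
#'   `comparison`, `importance`, `top5`), the tables of the run, and
#'   `run_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "wc_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # --- data ---
  if (!is.null(config$paths)) {
    raw <- ingest_logs(config$paths$sessions, config$paths$daily)
    truth <- NULL
  } else {
    gen <- config$generator
    gen$seed <- seed
    cohort <- generate_cohort(gen)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    raw <- cohort[c("sessions", "daily")]
    truth <- cohort$truth
  }
  log_stage("simulate", "%d sessions, %d participant-days",
            nrow(raw$sessions), nrow(raw$daily))

  inc <- apply_inclusion_rules(raw$sessions, raw$daily)
  write.csv(inc$report, file.path(out_dir, "inclusion_report.csv"),
            row.names = FALSE)
  log_stage("inclusion", "%d of %d participants retained",
            sum(inc$report$included), nrow(inc$report))

  daily_imp <- impute_missing(inc$daily)
  ft <- build_feature_table(inc$sessions, daily_imp)
  ft <- impute_missing(ft)
  log_stage("features", "%d rows x %d columns", nrow(ft), ncol(ft))

  unfolded <- markov_unfold(ft, n_lags = config$n_lags)
  log_stage("unfold", "%d rows x %d columns", nrow(unfolded), ncol(unfolded))

  fits <- list()
  comparisons <- list()
  importances <- list()
  pds <- list()
  top5 <- list()

  for (oc in config$outcomes) {
    md_main <- build_model_data(unfolded, oc, "MAIN", same_day = config$same_day) |>
      prune_model_data(config$correlation_threshold)
    md_act <- build_model_data(unfolded, oc, "ACTIONABLE", same_day = config$same_day) |>
      prune_model_data(config$correlation_threshold)
    log_stage("preprocess", "%s: MAIN %d predictors, ACTIONABLE %d predictors",
              oc, ncol(md_main) - 3, ncol(md_act) - 3)

    # group level
    base <- fit_baseline(md_main, seed = seed)
    g_main <- fit_group_model(md_main, config$group_learner, seed = seed)
    g_act <- fit_group_model(md_act, config$group_learner, seed = seed)
    imp <- permutation_importance(g_main, md_main, seed = seed)
    t5 <- top_k_features(imp, 5)
    lmm <- fit_lmm_top5(md_main, t5, seed = seed)
    fits[[paste0(oc, "_group_baseline")]] <- base
    fits[[paste0(oc, "_group_main")]] <- g_main
    fits[[paste0(oc, "_group_actionable")]] <- g_act
    fits[[paste0(oc, "_group_lmm_top5")]] <- lmm
    importances[[paste0(oc, "_group_main")]] <- imp
    top5[[oc]] <- t5
    for (f in head(t5, 3)) {
      pds[[paste0(oc, "_", f)]] <- tryCatch(
        partial_dependence(g_main, md_main, f), error = function(e) NULL)
    }
    pds <- Filter(Negate(is.null), pds)
    log_stage("fit", "%s group: baseline %.3f, MAIN %.3f, ACTIONABLE %.3f, LMM-top5 %.3f",
              oc, base$rmse, g_main$rmse, g_act$rmse, lmm$rmse)

    # individual level
    ind_main <- fit_individual_models(
      md_main, learners = config$individual_learners,
      cv_folds = config$cv_folds, cv_repeats = config$cv_repeats,
      min_rows = config$min_rows, B = config$bootstrap_B, seed = seed)
    ind_imp <- lapply(ind_main, model_importance_scaled, data = md_main)
    agg_imp <- aggregate_individual_importance(ind_imp)
    importances[[paste0(oc, "_individual_aggregate")]] <- agg_imp
    own_t5 <- lapply(ind_imp, top_k_features, k = 5)
    ind_own5 <- fit_individual_linear(md_main, own_t5, label = "top5_individual",
                                      min_rows = config$min_rows,
                                      B = config$bootstrap_B, seed = seed)
    ind_grp5 <- fit_individual_linear(md_main, t5, label = "top5_group",
                                      min_rows = config$min_rows,
                                      B = config$bootstrap_B, seed = seed)
    ind_base <- fit_individual_linear(md_main, character(0), label = "baseline",
                                      min_rows = config$min_rows,
                                      B = config$bootstrap_B, seed = seed)
    for (nm in names(ind_main)) fits[[paste0(oc, "_ind_main_", nm)]] <- ind_main[[nm]]
    for (nm in names(ind_own5)) fits[[paste0(oc, "_ind_own5_", nm)]] <- ind_own5[[nm]]
    for (nm in names(ind_grp5)) fits[[paste0(oc, "_ind_grp5_", nm)]] <- ind_grp5[[nm]]
    for (nm in names(ind_base)) fits[[paste0(oc, "_ind_base_", nm)]] <- ind_base[[nm]]

    rmse_tbl <- bind_rows(
      lapply(list(MAIN = ind_main, top5_individual = ind_own5,
                  top5_group = ind_grp5, baseline = ind_base),
             function(l) bind_rows(lapply(l, fit_glance_row)))) |>
      mutate(model_type = .data$variable_set) |>
      select("participant_id", "model_type", "rmse")
    comparisons[[oc]] <- compare_model_types(rmse_tbl, adjust = config$adjust)
    log_stage("compare", "%s: %s", oc,
              paste(sprintf("%s %.3f%s", comparisons[[oc]]$means$model_type,
                            comparisons[[oc]]$means$mean_rmse,
                            comparisons[[oc]]$means$letters), collapse = ", "))
  }

  paths <- render_report(fits, comparisons, importances, pds, out_dir)
  all_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- tibble(file = sub(paste0("^", out_dir, "/?"), "", all_files),
                     md5 = unname(tools::md5sum(all_files)))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  log_stage("report", "%d artifacts written to %s", length(all_files), out_dir)

  invisible(list(run_dir = out_dir, fits = fits, comparison = comparisons,
                 importance = importances, top5 = top5, truth = truth,
                 unfolded = unfolded))
}
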