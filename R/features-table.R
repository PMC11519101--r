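#' Variable manifest of the daily feature table
#'
#' Machine-readable description of every engineered variable: its category,
#' whether it is dynamic (lag-stacked during unfolding) or a static subject
#' characteristic, whether it is already known at the morning observation
#' (sleep, wellness, HRV and resting-HR readings, weekday) or only after it
#' (that day's training and diet), its variable-set membership (MAIN /
#' ACTIONABLE), whether it is a planned interaction column, and the outcome
#' family it derives from (used to block same-day leakage into the matching
#' outcome).
#'
#' The ACTIONABLE set is the MAIN set minus the readouts an athlete or coach
#' cannot directly manipulate: the centered recovery score itself, the
#' sleep-quality score and the sleep-index columns built from it, and every
#' resting HRV / resting HR column.
#'
#' @param include_tf Include the optional training-feeling pass-through
#'   column.
#' @return Tibble with columns `variable`, `category`, `dynamic`, `morning`,
#'   `main`, `actionable`, `interaction`, `family`.
#' @export
variable_manifest <- function(include_tf = FALSE) {
  row <- function(variable, category, family, dynamic = TRUE, morning = FALSE,
                  main = TRUE, interaction = FALSE) {
    tibble(variable = variable, category = category, family = family,
           dynamic = dynamic, morning = morning, main = main,
           interaction = interaction)
  }
  m <- bind_rows(
    row(c("duration_min", "tl", "srpe_max", "srpe_wmean", "n_workouts",
          "consec_days", "fasted", "tl_monotony7", "tl_strain7", "tl_ewma7",
          "tl_ma7", "tl_max7"), "training", "training"),
    row(paste0("mod_", c("swim", "bike", "run", "strength", "other")),
        "training", "training"),
    row(paste0("dow_", c("mon", "tue", "wed", "thu", "fri", "sat", "sun")),
        "training", "other", dynamic = FALSE, morning = TRUE),
    row(c("kcal_per_kg", "cho_g_per_kg", "fat_g_per_kg", "protein_g_per_kg",
          "pre_ex_cho_g", "cho_ma3", "cho_ma7", "fat_ma3", "fat_ma7",
          "protein_ma3", "protein_ma7", "kcal_ma3", "kcal_ma7", "cho_sd7",
          "cho_monotony7"), "dietary", "diet"),
    row(c("sleep_h", "sleep_h_ma7"), "sleep", "sleep", morning = TRUE),
    row(c("sleep_index", "sleep_index_ma7", "sleep_quality"), "sleep",
        "sleep_quality", morning = TRUE),
    row(c("soreness", "life_stress"), "subjective", "wellness", morning = TRUE),
    row("am_prs_c", "subjective", "prs", morning = TRUE),
    row(c("ln_rmssd", "hrv_change", "hrv_ewma7"), "non_exercise", "hrv",
        morning = TRUE),
    row(c("resting_hr", "rhr_change", "rhr_ewma7"), "non_exercise", "hr",
        morning = TRUE),
    row("ix_tl7_cho3", "interaction", "diet", interaction = TRUE),
    row("ix_mono_cho3", "interaction", "diet", interaction = TRUE),
    row("ix_tl1_sleep", "interaction", "sleep", morning = TRUE, interaction = TRUE),
    row("ix_tl1_prs1", "interaction", "prs", morning = TRUE, interaction = TRUE),
    row("body_mass_kg", "subject", "other", dynamic = FALSE, morning = TRUE)
  )
  if (include_tf) m <- bind_rows(m, row("tf", "training", "training", morning = TRUE))
  # ACTIONABLE: drop recovery/HRV/HR readouts and the sleep-quality-derived columns
  m$actionable <- m$main & !(m$family %in% c("prs", "hrv", "hr", "sleep_quality"))
  m
}

# exponentially weighted moving average seeded at the first value
ewma <- function(x, span = 7) {
  alpha <- 2 / (span + 1)
  if (length(x) <= 1) return(x)
  c(x[1], as.numeric(stats::filter(alpha * x[-1], 1 - alpha,
                                   method = "recursive", init = x[1])))
}

#' Build the per-participant-day feature table
#'
#' Computes every modelling variable from the raw session and daily logs:
#' daily training aggregates (load, highest and duration-weighted session
#' RPE, workout count, modality and fasted flags, consecutive training
#' days), 7-day rolling load metrics (monotony, strain, EWMA, moving
#' average, single-day maximum), dietary dailies with 3- and 7-day means
#' plus carbohydrate variability and monotony, the sleep index and 7-day
#' sleep means, day-over-day changes and 7-day EWMAs of Ln rMSSD and
#' resting HR, wellness scores, per-participant-centered AM PRS, weekday
#' indicator columns, the planned interaction columns (literal products of
#' their parents), and forward-filled body mass.
#'
#' Rest days contribute zero load to the rolling windows; rolling columns
#' are `NA` (not zero) during each participant's warm-up window. Raw logs
#' should be imputed first (see [impute_missing()]): `NA`s in inputs
#' propagate into derived columns.
#'
#' @param sessions Session log tibble (see [generate_cohort()] for schema);
#'   may be empty.
#' @param daily Daily log tibble, one row per participant-day,
#'   calendar-complete per participant.
#' @return Feature tibble, one row per participant-day, with the variable
#'   manifest attached as attribute `"manifest"` (see [variable_manifest()]
#'   and [feature_manifest()]).
#' @export
build_feature_table <- function(sessions, daily) {
  need <- c("participant_id", "date", "kcal_per_kg", "cho_g_per_kg",
            "fat_g_per_kg", "protein_g_per_kg", "sleep_h", "sleep_quality",
            "soreness", "life_stress", "am_prs", "ln_rmssd", "resting_hr",
            "body_mass_kg")
  missing_cols <- setdiff(need, names(daily))
  if (length(missing_cols))
    stop_validation(paste("daily log lacks required column(s):",
                          paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(daily[c("participant_id", "date")]))
    stop_validation("daily log has duplicate participant-day rows")
  daily <- daily |> arrange(.data$participant_id, .data$date)
  has_tf <- "tf" %in% names(daily)

  day_train <- aggregate_daily(sessions)
  ft <- daily |>
    left_join(day_train, by = c("participant_id", "date")) |>
    mutate(across(c("duration_min", "tl", "srpe_max", "srpe_wmean",
                    "pre_ex_cho_g"), ~ tidyr::replace_na(.x, 0)),
           n_workouts = tidyr::replace_na(.data$n_workouts, 0L),
           across(dplyr::starts_with("mod_"), ~ tidyr::replace_na(.x, FALSE)),
           fasted = tidyr::replace_na(.data$fasted, FALSE))

  per_part <- ft |>
    group_by(.data$participant_id) |>
    group_modify(function(d, key) {
      assert_sorted_gapfree(d$date, paste("participant", key$participant_id))
      load <- rolling_load_metrics(d$tl, window = 7)
      dietr <- rolling_diet_metrics(d, dates = NULL)
      d |>
        bind_cols(load, dietr) |>
        mutate(
          consec_days = consecutive_training_days(.data$tl),
          sleep_index = sleep_index(.data$sleep_h, .data$sleep_quality),
          sleep_h_ma7 = roll_stat(.data$sleep_h, 7, mean),
          sleep_index_ma7 = roll_stat(.data$sleep_index, 7, mean),
          hrv_change = hrv_change(.data$ln_rmssd),
          hrv_ewma7 = ewma(.data$ln_rmssd, span = 7),
          rhr_change = hrv_change(.data$resting_hr),
          rhr_ewma7 = ewma(.data$resting_hr, span = 7),
          body_mass_kg = cummax_ffill(.data$body_mass_kg)
        )
    }) |>
    ungroup()

  per_part <- per_part |>
    mutate(am_prs_c = center_by_participant(.data$am_prs, .data$participant_id))

  wd <- as.integer(format(per_part$date, "%u")) # 1 = Monday
  dows <- c("mon", "tue", "wed", "thu", "fri", "sat", "sun")
  for (i in 1:7) per_part[[paste0("dow_", dows[i])]] <- wd == i

  per_part <- per_part |>
    group_by(.data$participant_id) |>
    mutate(
      ix_tl7_cho3 = .data$tl_ma7 * .data$cho_ma3,
      ix_mono_cho3 = .data$tl_monotony7 * .data$cho_ma3,
      ix_tl1_sleep = dplyr::lag(.data$tl) * .data$sleep_h,
      ix_tl1_prs1 = dplyr::lag(.data$tl) * dplyr::lag(.data$am_prs_c)
    ) |>
    ungroup()

  manifest <- variable_manifest(include_tf = has_tf)
  keep <- c("participant_id", "date", "am_prs", manifest$variable)
  out <- per_part |> select(dplyr::all_of(keep))
  attr(out, "manifest") <- manifest
  out
}

#' Retrieve the manifest attached to a feature table
#'
#' @param ft A feature table from [build_feature_table()] (or an unfolded
#'   dataset carrying a manifest).
#' @return The manifest tibble.
#' @export
feature_manifest <- function(ft) {
  m <- attr(ft, "manifest")
  if (is.null(m)) stop_validation("no manifest attached; build the table with build_feature_table()")
  m
}
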