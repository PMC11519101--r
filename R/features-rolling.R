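# Rolling-window features over one participant's calendar-complete series.
# All windows are trailing and include the current day; a window statistic
# is only emitted once its full window is available (warm-up days are NA).

roll_stat <- function(x, width, fun) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n >= width) {
    for (t in width:n) out[t] <- fun(x[(t - width + 1):t])
  }
  out
}

#' Rolling training-load metrics
#'
#' Seven-day trailing measures of the daily training-load series of one
#' participant: training monotony (window mean divided by sample SD of the
#' daily loads), training strain (window load sum times monotony), the
#' exponentially weighted moving average with smoothing `alpha = 2/(span+1)`
#' seeded at the first observation, the plain moving average, and the
#' highest single-day load in the window. Rest days must be present as
#' zero-load days: monotony is only meaningful when easy days count as
#' low-load days. When the window SD is zero (perfectly uniform loading)
#' monotony and strain are `NA`; downstream imputation treats them like any
#' other missing value.
#'
#' @param tl Numeric daily training-load series, chronologically ordered and
#'   calendar-complete (rest days as 0).
#' @param dates Optional dates for gap checking.
#' @param window Trailing window width in days (default 7).
#' @param span EWMA span (default = `window`).
#' @return Tibble with columns `tl_monotony7`, `tl_strain7`, `tl_ewma7`,
#'   `tl_ma7`, `tl_max7`; window statistics are `NA` on the first
#'   `window - 1` days, the EWMA runs from day 1.
#' @export
#' @examples
#' rolling_load_metrics(c(100, 200, 300, 400, 500, 600, 700))
rolling_load_metrics <- function(tl, dates = NULL, window = 7, span = window) {
  if (!is.null(dates)) assert_sorted_gapfree(dates, "training-load")
  if (anyNA(tl)) stop_validation("training-load series must be NA-free (rest days are zeros)")
  m <- roll_stat(tl, window, mean)
  s <- roll_stat(tl, window, sd)
  monotony <- ifelse(!is.na(s) & s > 0, m / s, NA_real_)
  strain <- roll_stat(tl, window, sum) * monotony
  alpha <- 2 / (span + 1)
  # recursion ewma_t = alpha * x_t + (1 - alpha) * ewma_{t-1}, seeded at x_1
  ewma <- if (length(tl) > 1) {
    c(tl[1], as.numeric(stats::filter(alpha * tl[-1], 1 - alpha,
                                      method = "recursive", init = tl[1])))
  } else tl
  tibble(
    tl_monotony7 = monotony,
    tl_strain7 = strain,
    tl_ewma7 = ewma,
    tl_ma7 = m,
    tl_max7 = roll_stat(tl, window, max)
  )
}

#' Rolling dietary-intake metrics
#'
#' Trailing 3- and 7-day means of carbohydrate, fat, protein and energy
#' intake, the 7-day sample SD of carbohydrate intake, and carbohydrate
#' monotony (7-day mean divided by 7-day SD, the dietary analogue of
#' training monotony; `NA` when the SD is zero).
#'
#' @param diet Tibble (one participant, chronologically ordered,
#'   calendar-complete) with columns `cho_g_per_kg`, `fat_g_per_kg`,
#'   `protein_g_per_kg`, `kcal_per_kg`.
#' @param dates Optional dates for gap checking.
#' @return Tibble of `*_ma3`, `*_ma7` for the four intakes plus `cho_sd7`
#'   and `cho_monotony7`; warm-up days are `NA`.
#' @export
rolling_diet_metrics <- function(diet, dates = NULL) {
  if (!is.null(dates)) assert_sorted_gapfree(dates, "diet")
  need <- c("cho_g_per_kg", "fat_g_per_kg", "protein_g_per_kg", "kcal_per_kg")
  missing_cols <- setdiff(need, names(diet))
  if (length(missing_cols))
    stop_validation(paste("diet table lacks columns:", paste(missing_cols, collapse = ", ")))
  out <- tibble(.rows = nrow(diet))
  for (col in need) {
    short <- sub("_g_per_kg$|_per_kg$", "", col)
    out[[paste0(short, "_ma3")]] <- roll_stat(diet[[col]], 3, mean)
    out[[paste0(short, "_ma7")]] <- roll_stat(diet[[col]], 7, mean)
  }
  cho_m <- roll_stat(diet$cho_g_per_kg, 7, mean)
  cho_s <- roll_stat(diet$cho_g_per_kg, 7, sd)
  out$cho_sd7 <- cho_s
  out$cho_monotony7 <- ifelse(!is.na(cho_s) & cho_s > 0, cho_m / cho_s, NA_real_)
  out
}

#' Day-over-day change of a series
#'
#' First difference `x_t - x_{t-1}` of one participant's chronologically
#' ordered series; the first day is `NA`.
#'
#' @param x Numeric series.
#' @param dates Optional dates for gap checking.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' hrv_change(c(4.0, 4.2, 4.1)) # NA 0.2 -0.1
hrv_change <- function(x, dates = NULL) {
  if (!is.null(dates)) assert_sorted_gapfree(dates, "HRV")
  c(NA_real_, diff(x))
}

#' Count consecutive training days
#'
#' Running streak length: increments on each day with positive load, resets
#' to zero on rest days.
#'
#' @param tl Daily training-load series (calendar-complete).
#' @return Integer vector of streak lengths.
#' @export
#' @examples
#' consecutive_training_days(c(100, 100, 0, 100)) # 1 2 0 1
consecutive_training_days <- function(tl) {
  out <- integer(length(tl))
  streak <- 0L
  for (t in seq_along(tl)) {
    streak <- if (!is.na(tl[t]) && tl[t] > 0) streak + 1L else 0L
    out[t] <- streak
  }
  out
}

#' Center values around each participant's mean
#'
#' Subtracts the per-participant mean (computed over non-missing entries)
#' so every participant's centered series has mean zero; missing entries
#' stay missing.
#'
#' @param values Numeric vector.
#' @param participant_id Vector of the same length grouping values by athlete.
#' @return Centered numeric vector.
#' @export
#' @examples
#' center_by_participant(c(60, 70, 80), rep("a", 3)) # -10 0 10
center_by_participant <- function(values, participant_id) {
  if (length(values) != length(participant_id))
    stop_validation("values and participant_id must have equal length")
  means <- tapply(values, participant_id, mean, na.rm = TRUE)
  if (any(is.na(means)))
    stop_validation(paste("participant(s) with all-missing values:",
                          paste(names(means)[is.na(means)], collapse = ", ")))
  values - as.numeric(means[as.character(participant_id)])
}
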