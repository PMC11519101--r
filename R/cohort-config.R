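#' Configuration for the synthetic athlete cohort generator
#'
#' Bundles every knob of the simulator into a validated object. Defaults
#' describe a cohort of 43 endurance athletes tracked daily for 12 weeks,
#' with weekly training periodicity, AR(1) heart-rate-variability dynamics
#' with participant-specific baselines, wellness scores driven by recent
#' load and sleep, and a small MCAR missingness rate in the predictor logs.
#'
#' @param n_participants Number of athletes (>= 2).
#' @param n_days Days of tracking per athlete (>= 21; rolling features need a
#'   warm-up window).
#' @param missing_rate Proportion of eligible predictor cells blanked at
#'   random, in `[0, 0.2)`. Morning outcome readings (AM PRS, Ln rMSSD) are
#'   never blanked.
#' @param weekly_pattern Data frame with columns `weekday` (1 = Monday ..
#'   7 = Sunday), `train_prob` (probability of training that weekday) and
#'   `volume_mult` (relative training-duration multiplier). Defaults put
#'   longer sessions on weekends and a ~0.15 rest probability on weekdays.
#' @param effect_sizes Named list of generative coefficients, see
#'   [default_effect_sizes()].
#' @param heterogeneity_sd SD of per-athlete deviations added to the three
#'   wellness coefficients of the AM PRS model (`prs_soreness`, `prs_stress`,
#'   `prs_sleep_quality`). 0 disables heterogeneity, so every athlete shares
#'   the population coefficients; values comparable to the coefficient
#'   magnitudes make the athletes' key predictors genuinely different.
#' @param noise_sd_prs Residual SD of the AM PRS innovation (0-100 scale).
#'   `NULL` (default) derives it so the population SD of centered AM PRS is
#'   steered toward `prs_sd_target`.
#' @param prs_sd_target Target SD of centered AM PRS used when
#'   `noise_sd_prs` is `NULL`. Default 14.3.
#' @param hrv_phi_range Interval in (0, 1) from which each athlete's AR(1)
#'   persistence for Ln rMSSD is drawn uniformly.
#' @param hrv_noise_sd Innovation SD of the Ln rMSSD process.
#' @param seed Integer seed; identical configs with identical seeds yield
#'   byte-identical cohorts.
#'
#' @return A list of class `wc_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 4, n_days = 28, seed = 7)
#' cfg$n_days
cohort_config <- function(n_participants = 43,
                          n_days = 84,
                          missing_rate = 0.024,
                          weekly_pattern = default_weekly_pattern(),
                          effect_sizes = default_effect_sizes(),
                          heterogeneity_sd = 0,
                          noise_sd_prs = NULL,
                          prs_sd_target = 14.3,
                          hrv_phi_range = c(0.65, 0.85),
                          hrv_noise_sd = 0.25,
                          seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 2)
    stop_config("n_participants", "must be >= 2")
  if (!is.numeric(n_days) || n_days < 21)
    stop_config("n_days", "must be >= 21 (rolling features need a warm-up window)")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 0.2)
    stop_config("missing_rate", "must lie in [0, 0.2)")
  if (!is.data.frame(weekly_pattern) ||
      !all(c("weekday", "train_prob", "volume_mult") %in% names(weekly_pattern)) ||
      nrow(weekly_pattern) != 7)
    stop_config("weekly_pattern", "must be a 7-row data frame with weekday, train_prob, volume_mult")
  if (any(weekly_pattern$train_prob < 0 | weekly_pattern$train_prob > 1))
    stop_config("weekly_pattern", "train_prob must lie in [0, 1]")
  es <- default_effect_sizes()
  unknown <- setdiff(names(effect_sizes), names(es))
  if (length(unknown))
    stop_config("effect_sizes", paste("has unknown coefficients:", paste(unknown, collapse = ", ")))
  es[names(effect_sizes)] <- effect_sizes
  if (!is.numeric(heterogeneity_sd) || heterogeneity_sd < 0)
    stop_config("heterogeneity_sd", "must be >= 0")
  if (!is.null(noise_sd_prs) && (!is.numeric(noise_sd_prs) || noise_sd_prs < 0))
    stop_config("noise_sd_prs", "must be >= 0")
  if (length(hrv_phi_range) != 2 || hrv_phi_range[1] <= 0 || hrv_phi_range[2] >= 1 ||
      hrv_phi_range[1] > hrv_phi_range[2])
    stop_config("hrv_phi_range", "must be an increasing interval inside (0, 1)")
  if (!is.numeric(hrv_noise_sd) || hrv_noise_sd <= 0)
    stop_config("hrv_noise_sd", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_config("seed", "must be a single integer")

  structure(list(
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    missing_rate = missing_rate,
    weekly_pattern = as_tibble(weekly_pattern),
    effect_sizes = es,
    heterogeneity_sd = heterogeneity_sd,
    noise_sd_prs = noise_sd_prs,
    prs_sd_target = prs_sd_target,
    hrv_phi_range = hrv_phi_range,
    hrv_noise_sd = hrv_noise_sd,
    seed = as.integer(seed)
  ), class = "wc_cohort_config")
}

#' Default weekly training pattern
#'
#' Weekday rest probability ~0.15 with shorter sessions; weekend days train
#' almost always and carry higher duration multipliers (the long ride/run),
#' reflecting the weekly cycle most amateur endurance schedules follow.
#'
#' @return Tibble with columns `weekday`, `train_prob`, `volume_mult`.
#' @export
default_weekly_pattern <- function() {
  tibble(
    weekday = 1:7, # 1 = Monday
    train_prob = c(0.85, 0.85, 0.85, 0.85, 0.85, 0.95, 0.95),
    volume_mult = c(0.8, 0.8, 0.8, 0.8, 0.8, 1.6, 1.4)
  )
}

#' Default generative effect sizes
#'
#' Coefficients of the two outcome models the simulator uses. AM PRS (0-100)
#' responds negatively to muscle soreness and life stress, positively to
#' subjective sleep quality, and carries day-to-day persistence through
#' autoregressive terms on its own centered value one and two days back
#' (so yesterday's and the day before's scores both matter); training load
#' acts on PRS only
#' indirectly, through soreness. Ln rMSSD is mean-reverting AR(1) around the
#' athlete's baseline, depressed by the previous day's training load and
#' nudged up by longer sleep (both entered as within-athlete z-scores).
#'
#' @return Named list of coefficients:
#' \describe{
#'   \item{prs_soreness}{PRS points per soreness point above the athlete's mean (default -3).}
#'   \item{prs_stress}{PRS points per life-stress point (default -2).}
#'   \item{prs_sleep_quality}{PRS points per sleep-quality point (default 2).}
#'   \item{prs_ar1}{persistence of centered AM PRS on the previous day (default 0.35).}
#'   \item{prs_ar2}{persistence on the day before that (default 0.15), so
#'     the two previous mornings' scores are both genuinely informative.}
#'   \item{hrv_load}{Ln rMSSD units per z-score of previous-day load (default -0.03).}
#'   \item{hrv_sleep}{Ln rMSSD units per z-score of last night's sleep (default 0.02).}
#' }
#' @export
default_effect_sizes <- function() {
  list(
    prs_soreness = -3,
    prs_stress = -2,
    prs_sleep_quality = 2,
    prs_ar1 = 0.35,
    prs_ar2 = 0.15,
    hrv_load = -0.03,
    hrv_sleep = 0.02
  )
}

#' Zero out every generative effect
#'
#' Convenience for null-cohort simulations: all outcome-model coefficients
#' set to 0, so AM PRS is pure noise around each athlete's mean and Ln rMSSD
#' is covariate-free AR(1). Downstream models fit on such a cohort must not
#' beat the intercept-only baseline beyond noise.
#'
#' @return Named list in the shape of [default_effect_sizes()], all zeros.
#' @export
null_effect_sizes <- function() {
  es <- default_effect_sizes()
  lapply(es, function(x) 0)
}
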