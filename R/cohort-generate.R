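#' Generate a synthetic multi-athlete daily-log cohort
#'
#' Simulates per-workout session logs and per-day diet/sleep/wellness/HRV
#' logs for a cohort of endurance athletes, with known generative
#' coefficients so that every downstream stage (feature engineering,
#' unfolding, modelling, importance) can be tested against ground truth.
#' Athlete profiles (training volume, diet means, sleep habit, HRV baseline
#' and AR(1) persistence, personal outcome coefficients) are drawn once per
#' athlete; daily covariates follow the weekly training pattern; the two
#' outcomes are produced by [simulate_outcomes()]; MCAR missingness is then
#' applied to predictor cells by [apply_missingness()].
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements
#' \describe{
#'   \item{sessions}{tibble of workouts: `participant_id`, `date`,
#'     `modality`, `duration_min`, `rpe` (0-100 CR100), `pre_ex_cho_g`.}
#'   \item{daily}{tibble of one row per participant-day: diet totals
#'     (`kcal_per_kg`, `cho_g_per_kg`, `fat_g_per_kg`, `protein_g_per_kg`),
#'     `sleep_h`, `sleep_quality` (1-7), `soreness` (1-10), `life_stress`
#'     (1-7), `am_prs` (0-100), `ln_rmssd`, `resting_hr`, `body_mass_kg`.}
#'   \item{truth}{`wc_ground_truth`: athlete profiles (with personal
#'     coefficients), the global effect sizes, and the truly predictive
#'     feature families per outcome.}
#' }
#' Identical `(config, seed)` give byte-identical output.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 3, n_days = 28, seed = 2))
#' nrow(cohort$daily) # 3 x 28
generate_cohort <- function(config) {
  if (!inherits(config, "wc_cohort_config"))
    stop_config("config", "must be created with cohort_config()")

  profiles <- draw_profiles(config)
  start_date <- as.Date("2024-01-01") # a Monday, aligning weekday 1
  dates <- start_date + seq_len(config$n_days) - 1

  set.seed(child_seed(config$seed, "sessions"))
  per_part <- lapply(seq_len(config$n_participants), function(i) {
    simulate_participant_days(profiles[i, ], dates, config)
  })
  sessions <- bind_rows(lapply(per_part, `[[`, "sessions"))
  covars <- bind_rows(lapply(per_part, `[[`, "daily"))

  out <- simulate_outcomes(profiles, covars, config)
  daily <- covars |>
    left_join(out, by = c("participant_id", "date")) |>
    mutate(resting_hr = .data$rhr) |>
    select(-"rhr", -"tl") |>
    relocate("participant_id", "date")

  daily <- apply_missingness(daily, config$missing_rate,
                             seed = child_seed(config$seed, "missingness"))

  truth <- structure(list(
    profiles = profiles,
    effect_sizes = config$effect_sizes,
    # the truly predictive families per outcome: direct drivers, their
    # deterministic components and readouts, and generative parents,
    # applied uniformly (training load = duration x sRPE drives both
    # soreness and the HRV state; resting HR reads the HRV state out;
    # sleep duration drives sleep quality, the sleep index and the HRV
    # state). Diet, life stress (for HRV), modality identity, weekday and
    # body mass carry no generative path to the outcome beyond incidental
    # correlation and are never listed.
    true_drivers = list(
      am_prs = c("am_prs_c", "soreness", "life_stress",
                 sleep_family(), load_family()),
      hrv_change = c("ln_rmssd", "hrv_change", "hrv_ewma7", "resting_hr",
                     "rhr_change", "rhr_ewma7", "soreness",
                     sleep_family(), load_family())
    )
  ), class = "wc_ground_truth")

  list(sessions = sessions, daily = daily, truth = truth)
}

# athlete-level draws: training volume and diet/sleep means emulate the
# descriptive statistics of an amateur-to-elite endurance cohort
draw_profiles <- function(config) {
  set.seed(child_seed(config$seed, "profiles"))
  n <- config$n_participants
  es <- config$effect_sizes
  het <- config$heterogeneity_sd
  profiles <- tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    weekly_hours = rnorm_clip(n, 11.8, 3.3, 7, 24),
    prs_mean = rnorm_clip(n, 70, 8, 45, 92),
    hrv_baseline = runif(n, max(3.5, 3.0), min(4.5, 5.0)),
    hrv_phi = runif(n, config$hrv_phi_range[1], config$hrv_phi_range[2]),
    rhr_baseline = rnorm_clip(n, 52, 6, 38, 72),
    kcal_per_kg_mean = rnorm_clip(n, 39.6, 8.7, 22, 68),
    cho_g_per_kg_mean = rnorm_clip(n, 4.1, 1.5, 1.6, 9),
    protein_g_per_kg_mean = rnorm_clip(n, 1.9, 0.4, 0.9, 3.4),
    fat_g_per_kg_mean = rnorm_clip(n, 1.7, 0.5, 0.6, 3.4),
    sleep_mean_h = rnorm_clip(n, 7.5, 0.7, 5.6, 9.4),
    body_mass_kg = rnorm_clip(n, 72, 9, 48, 105)
  )
  # personal outcome coefficients: global betas plus athlete-specific noise
  profiles$beta_soreness <- es$prs_soreness + rnorm(n, 0, het)
  profiles$beta_stress <- es$prs_stress + rnorm(n, 0, het)
  profiles$beta_sleep_quality <- es$prs_sleep_quality + rnorm(n, 0, het)
  profiles$beta_ar1 <- clamp(rep(es$prs_ar1, n), -0.9, 0.9)
  profiles$beta_ar2 <- clamp(rep(es$prs_ar2, n), -0.9, 0.9)
  profiles
}

# one participant's training sessions and daily covariates (no outcomes yet)
simulate_participant_days <- function(profile, dates, config) {
  wp <- config$weekly_pattern
  nd <- length(dates)
  wd <- ((as.integer(dates) - as.integer(as.Date("2024-01-01"))) %% 7L) + 1L

  trains <- runif(nd) < wp$train_prob[wd]
  # expected weekly minutes match the athlete's habitual volume
  base_min <- profile$weekly_hours * 60 *
    wp$volume_mult[wd] / sum(wp$train_prob * wp$volume_mult)
  day_min <- ifelse(trains, pmax(20, round(base_min * rlnorm(nd, 0, 0.35))), 0)

  tl <- numeric(nd)
  modalities <- c("swim", "bike", "run", "strength", "other")
  mod_prob <- c(0.15, 0.40, 0.30, 0.10, 0.05)
  train_idx <- which(trains)
  sessions <- tibble(participant_id = character(0), date = as.Date(character(0)),
                     modality = character(0), duration_min = numeric(0),
                     rpe = numeric(0), pre_ex_cho_g = numeric(0))
  if (length(train_idx)) {
    # one session per training day, a second shorter one with p = 0.2
    two <- rbinom(length(train_idx), 1, 0.2) == 1
    a <- runif(length(train_idx), 0.55, 0.75)
    day_idx <- c(train_idx, train_idx[two])
    wts <- c(ifelse(two, a, 1), 1 - a[two])
    ord <- order(day_idx)
    day_idx <- day_idx[ord]; wts <- wts[ord]
    ns <- length(day_idx)
    durs <- pmax(15, round(day_min[day_idx] * wts))
    rpe <- clamp(round(rlnorm(ns, log(42), 0.30)), 10, 95)
    fasted <- runif(ns) < 0.3
    cho <- ifelse(fasted, runif(ns, 0, 4),
                  pmin(rgamma(ns, shape = 4, scale = 10), 150))
    sessions <- tibble(
      participant_id = profile$participant_id,
      date = dates[day_idx],
      modality = sample(modalities, ns, replace = TRUE, prob = mod_prob),
      duration_min = as.numeric(durs),
      rpe = as.numeric(rpe),
      pre_ex_cho_g = round(cho, 1)
    )
    loads <- durs * rpe / 10
    tl[sort(unique(day_idx))] <- as.numeric(tapply(loads, day_idx, sum))
  }

  sleep_h <- round(rnorm_clip(nd, profile$sleep_mean_h, 0.6, 4, 10.5), 2)
  sleep_z <- zscore(sleep_h)
  # wellness integers from binned latent gaussians
  sleep_quality <- clamp(round(4.5 + 1.3 * (0.8 * sleep_z + 0.6 * rnorm(nd))), 1, 7)
  # soreness reacts to yesterday's and the prior day's load
  lag1 <- c(0, head(tl, -1)); lag2 <- c(0, 0, head(tl, -2))
  sore_lat <- 0.9 * zscore(lag1 + 0.5 * lag2) - 0.4 * sleep_z + 0.6 * rnorm(nd)
  soreness <- clamp(round(5 + 1.8 * sore_lat), 1, 10)
  stress_e <- as.numeric(stats::filter(rnorm(nd), 0.3, method = "recursive"))
  life_stress <- clamp(round(3.5 + 1.2 * zscore(stress_e)), 1, 7)

  # mild coupling of intake to that day's load; diet is logged after training
  tl_z <- zscore(tl)
  cho <- round(rnorm_clip(nd, profile$cho_g_per_kg_mean, 0.8, 0.5, 12) + 0.15 * tl_z, 2)
  fat <- round(rnorm_clip(nd, profile$fat_g_per_kg_mean, 0.35, 0.3, 4), 2)
  protein <- round(rnorm_clip(nd, profile$protein_g_per_kg_mean, 0.25, 0.5, 4), 2)
  kcal <- round(rnorm_clip(nd, profile$kcal_per_kg_mean, 4, 15, 75) + 1.5 * tl_z, 1)

  # body mass recorded weekly, carried forward between entries
  bm <- rep(NA_real_, nd)
  weekly_idx <- seq(1, nd, by = 7)
  bm[weekly_idx] <- round(profile$body_mass_kg + cumsum(rnorm(length(weekly_idx), 0, 0.15)), 1)
  bm <- cummax_ffill(bm)

  daily <- tibble(
    participant_id = profile$participant_id,
    date = dates,
    tl = tl,
    kcal_per_kg = pmax(kcal, 10),
    cho_g_per_kg = pmax(cho, 0.3),
    fat_g_per_kg = fat,
    protein_g_per_kg = protein,
    sleep_h = sleep_h,
    sleep_quality = as.integer(sleep_quality),
    soreness = as.integer(soreness),
    life_stress = as.integer(life_stress),
    body_mass_kg = bm
  )
  list(sessions = sessions, daily = daily)
}

# variable families used in the ground-truth driver declaration
load_family <- function() {
  c("tl", "duration_min", "srpe_wmean", "srpe_max", "n_workouts",
    "consec_days", "tl_ewma7", "tl_ma7", "tl_max7", "tl_strain7",
    "tl_monotony7")
}
sleep_family <- function() {
  c("sleep_h", "sleep_quality", "sleep_index", "sleep_h_ma7",
    "sleep_index_ma7")
}

# last-observation-carried-forward for sparse body-mass entries
cummax_ffill <- function(x) {
  ok <- !is.na(x)
  if (!ok[1]) x[1] <- x[which(ok)[1]]
  idx <- cummax(ifelse(!is.na(x), seq_along(x), 0L))
  x[idx]
}

# one AR(1) mean-reversion step of the Ln rMSSD process
ar1_next <- function(x_prev, mu, phi, drive = 0, eps = 0) {
  mu + phi * (x_prev - mu) + drive + eps
}

#' Simulate the two outcome series for a cohort
#'
#' Given athlete profiles and already-simulated daily covariates, produces
#' morning perceived recovery status and resting Ln rMSSD. Ln rMSSD follows
#' a mean-reverting AR(1) around the athlete's baseline,
#' `x_t = mu + phi * (x_{t-1} - mu) + gamma * z(load_{t-1}) + delta * z(sleep_t) + eps_t`,
#' so the day-to-day change regresses negatively on the previous level
#' (lag-1 autocorrelation of the change is `(phi - 1) / 2` in the
#' covariate-free case). AM PRS is the athlete's mean plus wellness-driven
#' deviations with AR(1) persistence, clipped to `[0, 100]`; its residual SD
#' is either given (`noise_sd_prs`) or steered so the population SD of
#' centered AM PRS approaches `prs_sd_target`. Resting HR is generated as a
#' noisy inverse reflection of the same-morning HRV state.
#'
#' @param profiles Athlete profile tibble as built by [generate_cohort()]
#'   (one row per athlete, including personal coefficients).
#' @param covars Daily covariate tibble with `participant_id`, `date`, `tl`,
#'   `sleep_h`, `sleep_quality`, `soreness`, `life_stress`; every athlete
#'   must have the same number of days.
#' @param config A [cohort_config()] object (effect sizes, noise SDs, seed).
#' @return Tibble `participant_id`, `date`, `am_prs`, `ln_rmssd`, `rhr`.
#' @export
simulate_outcomes <- function(profiles, covars, config) {
  counts <- covars |> count(.data$participant_id)
  if (length(unique(counts$n)) != 1)
    stop_validation("covariate series are of unequal length across participants")
  if (!setequal(counts$participant_id, profiles$participant_id))
    stop_validation("covariate participants do not align with profiles")

  es <- config$effect_sizes
  set.seed(child_seed(config$seed, "outcomes"))
  res <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    cv <- covars |> filter(.data$participant_id == p$participant_id) |> arrange(.data$date)
    nd <- nrow(cv)

    # --- Ln rMSSD: AR(1) with covariate drive ---
    load_z <- zscore(c(0, head(cv$tl, -1)))
    sleep_z <- zscore(cv$sleep_h)
    drive <- es$hrv_load * load_z + es$hrv_sleep * sleep_z
    eps <- rnorm(nd, 0, config$hrv_noise_sd)
    x <- numeric(nd)
    stat_sd <- config$hrv_noise_sd / sqrt(1 - p$hrv_phi^2)
    x[1] <- p$hrv_baseline + rnorm(1, 0, stat_sd)
    for (t in 2:nd) {
      x[t] <- ar1_next(x[t - 1], p$hrv_baseline, p$hrv_phi, drive[t], eps[t])
    }
    x <- pmax(x, 0.5)

    # --- AM PRS: persistence + wellness signal + noise, clipped ---
    s <- p$beta_soreness * (cv$soreness - mean(cv$soreness)) +
      p$beta_stress * (cv$life_stress - mean(cv$life_stress)) +
      p$beta_sleep_quality * (cv$sleep_quality - mean(cv$sleep_quality))
    ar1 <- p$beta_ar1; ar2 <- p$beta_ar2
    sd_eps <- if (!is.null(config$noise_sd_prs)) {
      config$noise_sd_prs
    } else {
      # approximate stationary-variance steering for the AR(2) deviation
      sqrt(max(config$prs_sd_target^2 * (1 - ar1^2 - ar2^2) - var(s),
               (0.25 * config$prs_sd_target)^2))
    }
    dev <- numeric(nd)
    innov <- s + rnorm(nd, 0, sd_eps)
    dev[1] <- innov[1] / sqrt(max(1 - ar1^2 - ar2^2, 0.19))
    dev[2] <- ar1 * dev[1] + innov[2]
    if (nd > 2) for (t in 3:nd) dev[t] <- ar1 * dev[t - 1] + ar2 * dev[t - 2] + innov[t]
    prs <- clamp(round(p$prs_mean + dev), 0, 100)

    rhr <- round(p$rhr_baseline - 10 * (x - p$hrv_baseline) + rnorm(nd, 0, 1.5))

    tibble(participant_id = p$participant_id, date = cv$date,
           am_prs = as.numeric(prs), ln_rmssd = round(x, 3),
           rhr = as.numeric(rhr))
  })
  bind_rows(res)
}

#' Blank predictor cells at random
#'
#' Applies missing-completely-at-random blanking at the given rate to the
#' eligible cells of a daily-log table. Same-day outcome readings are never
#' blanked: the missingness this emulates lives in diet and wellness logs,
#' not in the morning outcome measurements.
#'
#' @param data Daily-log tibble.
#' @param missing_rate Proportion of eligible cells to blank, in `[0, 0.2)`.
#' @param seed Integer seed; the blank mask is reproducible.
#' @param protect Character vector of columns never blanked.
#' @return `data` with `NA`s inserted.
#' @export
apply_missingness <- function(data, missing_rate, seed,
                              protect = c("participant_id", "date",
                                          "am_prs", "ln_rmssd")) {
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 0.2)
    stop_config("missing_rate", "must lie in [0, 0.2)")
  if (missing_rate == 0) return(data)
  set.seed(seed)
  eligible <- setdiff(names(data), protect)
  for (col in eligible) {
    mask <- runif(nrow(data)) < missing_rate
    data[[col]][mask] <- NA
  }
  data
}
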