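#' Session training load (sRPE)
#'
#' Internal training load of one workout: the product of the session RPE
#' (0-100 CR100 scale) and its duration in minutes, divided by 10 to bring
#' the 100-point scale onto the conventional sRPE magnitude.
#'
#' @param duration_min Session duration in minutes (> 0).
#' @param rpe Session rating of perceived exertion, 0-100.
#' @return `duration_min * rpe / 10`, vectorised.
#' @export
#' @examples
#' session_load(60, 50) # 300
session_load <- function(duration_min, rpe) {
  if (any(duration_min <= 0, na.rm = TRUE))
    stop_domain("duration_min must be > 0")
  if (any(rpe < 0 | rpe > 100, na.rm = TRUE))
    stop_domain("rpe must lie in [0, 100]")
  duration_min * rpe / 10
}

#' Sleep index
#'
#' Product of sleep duration (hours) and subjective sleep quality (1-7),
#' a single number summarising quantity and quality of the night.
#'
#' @param sleep_h Sleep duration in hours (>= 0).
#' @param sleep_quality Subjective quality, integer scale 1-7.
#' @return `sleep_h * sleep_quality`, units h x points.
#' @export
#' @examples
#' sleep_index(7.5, 4) # 30
sleep_index <- function(sleep_h, sleep_quality) {
  if (any(sleep_quality < 1 | sleep_quality > 7, na.rm = TRUE))
    stop_domain("sleep_quality must lie in [1, 7]")
  if (any(sleep_h < 0, na.rm = TRUE))
    stop_domain("sleep_h must be >= 0")
  sleep_h * sleep_quality
}

#' Collapse a day's workouts into daily training fields
#'
#' Sums duration and load over the day's sessions, takes the highest single
#' session RPE and a duration-weighted mean RPE, duration-weights the
#' pre-exercise carbohydrate intake, unions the modality flags, and flags
#' the day as fasted-trained if any session was started with < 5 g
#' carbohydrate in the pre-exercise window. A day with no sessions is a rest
#' day: all training fields 0/FALSE, not an error.
#'
#' @param sessions Session tibble (possibly empty) for one or more
#'   participant-days: `participant_id`, `date`, `modality`, `duration_min`,
#'   `rpe`, `pre_ex_cho_g`.
#' @return Tibble with one row per participant-day present in `sessions`:
#'   `duration_min`, `tl`, `srpe_max`, `srpe_wmean`, `n_workouts`,
#'   `pre_ex_cho_g`, `fasted`, and logical modality flags `mod_*`.
#' @export
aggregate_daily <- function(sessions) {
  modalities <- c("swim", "bike", "run", "strength", "other")
  empty <- tibble(
    participant_id = character(), date = as.Date(character()),
    duration_min = numeric(), tl = numeric(), srpe_max = numeric(),
    srpe_wmean = numeric(), n_workouts = integer(),
    pre_ex_cho_g = numeric(), fasted = logical()
  )
  for (m in modalities) empty[[paste0("mod_", m)]] <- logical()
  if (nrow(sessions) == 0) return(empty)

  sessions |>
    mutate(load = session_load(.data$duration_min, .data$rpe),
           dur = .data$duration_min, # summarise() overwrites duration_min below
           sess_fasted = .data$pre_ex_cho_g < 5) |>
    group_by(.data$participant_id, .data$date) |>
    summarise(
      duration_min = sum(.data$dur),
      tl = sum(.data$load),
      srpe_max = max(.data$rpe),
      srpe_wmean = sum(.data$rpe * .data$dur) / sum(.data$dur),
      n_workouts = dplyr::n(),
      pre_ex_cho_g = sum(.data$pre_ex_cho_g * .data$dur) / sum(.data$dur),
      fasted = any(.data$sess_fasted),
      !!!setNames(
        lapply(modalities, function(m) rlang::expr(any(.data$modality == !!m))),
        paste0("mod_", modalities)
      ),
      .groups = "drop"
    )
}
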