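# internal helpers shared across modules

# deterministic child seed derivation so one pipeline seed fans out to
# independent per-stage streams; kept below .Machine$integer.max
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    profiles = 11L, sessions = 23L, covariates = 37L, outcomes = 41L,
    missingness = 53L, folds = 67L, bootstrap = 71L, permutation = 83L,
    tuning = 97L, replicate = 101L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647L)
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "wellcast_config_error")
}

stop_domain <- function(msg) {
  abort(msg, class = "wellcast_domain_error")
}

stop_validation <- function(msg) {
  abort(msg, class = "wellcast_validation_error")
}

# clip to interval
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# normal draw truncated by rejection-free clipping (adequate for cohort
# marginals; tails are physiologically implausible anyway)
rnorm_clip <- function(n, mean, sd, lo, hi) clamp(rnorm(n, mean, sd), lo, hi)

# standardize to z-scores, guarding zero variance
zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

assert_sorted_gapfree <- function(dates, what = "series") {
  if (is.unsorted(dates, strictly = TRUE)) {
    stop_validation(sprintf("%s dates must be strictly increasing", what))
  }
  if (length(dates) > 1 && any(diff(as.integer(as.Date(dates))) != 1L)) {
    stop_validation(sprintf("%s must be calendar-complete (no gapped dates)", what))
  }
  invisible(TRUE)
}
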