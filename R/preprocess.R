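#' Apply cohort inclusion rules
#'
#' Retains participants who trained at least `min_weekly_h` hours per week
#' on average, logged at least `min_logged` of their required daily fields,
#' and tracked for at least `min_days` days. Days whose dietary record is
#' essentially absent (3+ of the 4 intake fields missing) are treated as
#' incomplete tracking days: their dietary information is discarded (the
#' calendar row is kept as a placeholder so rolling windows stay
#' gap-free, and the gap is imputed later).
#'
#' @param sessions,daily Raw log tibbles.
#' @param min_weekly_h Minimum average weekly training volume, hours.
#' @param min_logged Minimum fraction of non-missing required daily fields.
#' @param min_days Minimum days of tracking.
#' @return List `sessions`, `daily` (filtered to included participants) and
#'   `report`, a tibble with per-participant `weekly_hours`,
#'   `logged_fraction`, `days_tracked`, `dropped_diet_days`, `included` and
#'   comma-separated exclusion `reasons`
#'   (`low_volume`, `low_logging`, `short_tracking`).
#' @export
apply_inclusion_rules <- function(sessions, daily, min_weekly_h = 6,
                                  min_logged = 0.85, min_days = 42) {
  required_cols <- intersect(
    c("kcal_per_kg", "cho_g_per_kg", "fat_g_per_kg", "protein_g_per_kg",
      "sleep_h", "sleep_quality", "soreness", "life_stress", "am_prs",
      "ln_rmssd", "resting_hr"),
    names(daily))
  diet_cols <- intersect(
    c("kcal_per_kg", "cho_g_per_kg", "fat_g_per_kg", "protein_g_per_kg"),
    names(daily))

  # incomplete diet days: discard the dietary record, keep the calendar row
  n_miss_diet <- rowSums(is.na(daily[diet_cols]))
  incomplete <- n_miss_diet >= 3
  daily[incomplete, diet_cols] <- NA

  vol <- sessions |>
    group_by(.data$participant_id) |>
    summarise(total_min = sum(.data$duration_min), .groups = "drop")
  report <- daily |>
    group_by(.data$participant_id) |>
    summarise(
      days_tracked = dplyr::n(),
      logged_fraction = mean(!is.na(as.matrix(pick(dplyr::all_of(required_cols))))),
      dropped_diet_days = sum(incomplete[daily$participant_id == .data$participant_id[1]]),
      .groups = "drop") |>
    left_join(vol, by = "participant_id") |>
    mutate(weekly_hours = tidyr::replace_na(.data$total_min, 0) / 60 /
             .data$days_tracked * 7) |>
    select(-"total_min")

  report <- report |>
    rowwise() |>
    mutate(reasons = paste(c(
      if (.data$weekly_hours < min_weekly_h) "low_volume",
      if (.data$logged_fraction < min_logged) "low_logging",
      if (.data$days_tracked < min_days) "short_tracking"
    ), collapse = ",")) |>
    ungroup() |>
    mutate(included = .data$reasons == "")

  keep <- report$participant_id[report$included]
  list(
    sessions = sessions |> filter(.data$participant_id %in% keep),
    daily = daily |> filter(.data$participant_id %in% keep),
    report = report
  )
}

#' Impute missing values within each participant
#'
#' Diet and training measures are filled by k-nearest-neighbour imputation
#' over the participant's own days, with distances computed on the
#' standardized columns that are complete for that participant; when no
#' usable neighbours exist, a within-participant linear-regression fallback
#' on the most correlated complete columns is used, and failing that the
#' participant median. All other variables are filled with the participant
#' median. Imputation never crosses participants.
#'
#' @param data Tibble with a `participant_id` column.
#' @param knn_cols Columns imputed by kNN/regression; defaults to the diet
#'   and training measures present in `data`.
#' @param k Number of neighbours (default 5).
#' @return `data` with no missing values in the imputable columns; tables
#'   without missing values are returned unchanged.
#' @export
impute_missing <- function(data, knn_cols = NULL, k = 5) {
  if (is.null(knn_cols)) {
    knn_cols <- intersect(
      c("kcal_per_kg", "cho_g_per_kg", "fat_g_per_kg", "protein_g_per_kg",
        "pre_ex_cho_g", "cho_ma3", "cho_ma7", "fat_ma3", "fat_ma7",
        "protein_ma3", "protein_ma7", "kcal_ma3", "kcal_ma7", "cho_sd7",
        "cho_monotony7", "duration_min", "tl", "srpe_max", "srpe_wmean",
        "tl_monotony7", "tl_strain7", "tl_ewma7", "tl_ma7", "tl_max7"),
      names(data))
  }
  if (!anyNA(data)) return(data)
  numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  attrs <- attributes(data)

  out <- data |>
    group_by(.data$participant_id) |>
    group_modify(function(d, key) impute_participant(d, key$participant_id,
                                                     knn_cols, numeric_cols, k)) |>
    ungroup()
  out <- refresh_interactions(out)
  attr(out, "manifest") <- attrs$manifest
  out
}

# keep planned interaction columns literal products of their (possibly
# freshly imputed) parents
refresh_interactions <- function(data) {
  if (all(c("ix_tl7_cho3", "tl_ma7", "cho_ma3") %in% names(data))) {
    data <- data |>
      group_by(.data$participant_id) |>
      mutate(
        ix_tl7_cho3 = .data$tl_ma7 * .data$cho_ma3,
        ix_mono_cho3 = .data$tl_monotony7 * .data$cho_ma3,
        ix_tl1_sleep = dplyr::lag(.data$tl) * .data$sleep_h,
        ix_tl1_prs1 = dplyr::lag(.data$tl) * dplyr::lag(.data$am_prs_c)
      ) |>
      ungroup()
    # day-one products have no lagged parent; fall back to participant median
    for (col in c("ix_tl1_sleep", "ix_tl1_prs1")) {
      med <- tapply(data[[col]], data$participant_id, median, na.rm = TRUE)
      miss <- is.na(data[[col]])
      data[[col]][miss] <- as.numeric(med[as.character(data$participant_id[miss])])
    }
  }
  data
}

impute_participant <- function(d, pid, knn_cols, numeric_cols, k) {
  target_cols <- names(d)[vapply(d, anyNA, logical(1))]
  complete_num <- intersect(numeric_cols, names(d)[!vapply(d, anyNA, logical(1))])
  for (col in target_cols) {
    x <- d[[col]]
    miss <- is.na(x)
    if (all(miss))
      stop_validation(sprintf("participant %s has column `%s` entirely missing", pid, col))
    if (col %in% knn_cols && length(complete_num) >= 1) {
      z <- scale(as.matrix(d[complete_num]))
      z[is.nan(z)] <- 0
      donors <- which(!miss)
      for (i in which(miss)) {
        dist2 <- colSums((t(z[donors, , drop = FALSE]) - z[i, ])^2)
        kk <- min(k, length(donors))
        nn <- donors[order(dist2)[seq_len(kk)]]
        if (length(nn)) {
          x[i] <- mean(x[nn])
        } else {
          x[i] <- regression_fallback(d, col, complete_num, i)
        }
      }
    } else {
      fill <- if (is.numeric(x)) median(x[!miss]) else {
        tab <- table(x[!miss]); names(tab)[which.max(tab)]
      }
      if (is.integer(x)) fill <- as.integer(round(as.numeric(fill)))
      if (is.logical(d[[col]])) fill <- as.logical(fill)
      x[miss] <- fill
    }
    d[[col]] <- x
  }
  d
}

# linear-regression fallback on the up-to-3 most correlated complete columns
regression_fallback <- function(d, col, complete_num, i) {
  obs <- !is.na(d[[col]])
  preds <- setdiff(complete_num, col)
  if (!length(preds) || sum(obs) < 4) return(median(d[[col]], na.rm = TRUE))
  r <- vapply(preds, function(p) abs(cor(d[[col]][obs], d[[p]][obs])), numeric(1))
  r[is.na(r)] <- 0
  use <- preds[order(-r)][seq_len(min(3, length(preds)))]
  fit <- lm(stats::reformulate(use, col), data = d[obs, ])
  as.numeric(predict(fit, d[i, ]))
}

#' Remove highly correlated predictors
#'
#' Iteratively finds the pair of columns with the largest absolute Pearson
#' correlation above the threshold and removes the member with the larger
#' mean absolute correlation against all remaining columns, until no pair
#' exceeds the threshold. Constant (zero-variance) columns are removed
#' first, since their correlations are undefined. Ties on the mean absolute
#' correlation are broken by dropping the later column (deterministic).
#'
#' @param x Data frame or matrix of numeric predictors (>= 3 rows).
#' @param threshold Absolute-correlation cutoff (default 0.85).
#' @return List with `x`, the pruned data, and `removed`, a tibble of
#'   `variable` and `reason` (`zero_variance` or `high_correlation`).
#' @export
prune_correlated <- function(x, threshold = 0.85) {
  xdf <- as.data.frame(x)
  if (nrow(xdf) < 3) stop_validation("pruning needs at least 3 rows")
  removed <- tibble(variable = character(), reason = character())

  sds <- vapply(xdf, function(v) sd(v, na.rm = TRUE), numeric(1))
  const <- names(xdf)[!is.finite(sds) | sds == 0]
  if (length(const)) {
    removed <- bind_rows(removed, tibble(variable = const, reason = "zero_variance"))
    xdf <- xdf[setdiff(names(xdf), const)]
  }
  if (ncol(xdf) >= 2) {
    C <- abs(cor(as.matrix(xdf), use = "pairwise.complete.obs"))
    C[is.na(C)] <- 0
    diag(C) <- 0
    keep <- colnames(C)
    while (length(keep) >= 2) {
      Ck <- C[keep, keep, drop = FALSE]
      mx <- max(Ck)
      if (mx <= threshold) break
      idx <- which(Ck == mx, arr.ind = TRUE)[1, ]
      i <- keep[idx[1]]; j <- keep[idx[2]]
      mean_i <- mean(Ck[i, setdiff(keep, i)])
      mean_j <- mean(Ck[j, setdiff(keep, j)])
      drop_var <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else
        keep[max(match(c(i, j), keep))]
      removed <- bind_rows(removed,
                           tibble(variable = drop_var, reason = "high_correlation"))
      keep <- setdiff(keep, drop_var)
    }
    xdf <- xdf[keep]
  }
  list(x = as_tibble(xdf), removed = removed)
}

#' Markov-unfold a feature table into independent observations
#'
#' Stacks lagged copies (lags 1..`n_lags`) of every dynamic column as new
#' columns (suffix `_lag<k>`; the unsuffixed column is the same-day value)
#' and discards the first `n_lags` rows of each participant, whose lags
#' would be undefined. Unfolding is strictly within participant: no lagged
#' cell ever crosses a participant boundary. Static subject characteristics
#' are carried through unchanged, so the dynamic block becomes
#' `n_lags + 1` times wider while each participant contributes
#' `n_days - n_lags` rows.
#'
#' @param ft Feature table from [build_feature_table()] (manifest attached),
#'   or any participant/date table with an explicit `manifest`.
#' @param n_lags Number of lagged copies (default 7; 0 is the identity).
#' @param manifest Variable manifest; defaults to the one attached to `ft`.
#' @return Unfolded tibble with the manifest and `n_lags` stored as
#'   attributes. Participants with `n_lags` rows or fewer are dropped with
#'   a warning.
#' @export
markov_unfold <- function(ft, n_lags = 7, manifest = feature_manifest(ft)) {
  if (n_lags < 0) stop_config("n_lags", "must be >= 0")
  dyn <- intersect(manifest$variable[manifest$dynamic], names(ft))
  ft <- ft |> arrange(.data$participant_id, .data$date)

  parts <- split(ft, ft$participant_id)
  too_short <- names(parts)[vapply(parts, nrow, integer(1)) <= n_lags]
  if (length(too_short)) {
    warn(paste("dropping participant(s) with too few rows to unfold:",
               paste(too_short, collapse = ", ")))
    parts <- parts[setdiff(names(parts), too_short)]
    if (!length(parts)) stop_validation("no participant has enough rows to unfold")
  }

  unfolded <- lapply(parts, function(d) {
    assert_sorted_gapfree(d$date, "participant")
    n <- nrow(d)
    if (n_lags > 0) {
      lag_blocks <- lapply(seq_len(n_lags), function(k) {
        blk <- d[pmax(seq_len(n) - k, 1), dyn, drop = FALSE]
        blk[seq_len(n) <= k, ] <- NA # undefined before day k+1
        names(blk) <- paste0(dyn, "_lag", k)
        blk
      })
      d <- bind_cols(d, lag_blocks)
      d <- d[(n_lags + 1):n, , drop = FALSE]
    }
    d
  })
  out <- bind_rows(unfolded)
  attr(out, "manifest") <- manifest
  attr(out, "n_lags") <- n_lags
  out
}

#' Select a variable set from an unfolded dataset
#'
#' Restricts the unfolded predictor columns to the requested variable set:
#' `MAIN` (all modelling variables), `ACTIONABLE` (the subset an athlete or
#' coach can directly manipulate; no recovery-score, sleep-quality-derived,
#' resting-HRV or resting-HR columns), or `TOP5`, which keeps exactly the
#' explicitly named (lagged) feature columns. Identity columns, the raw
#' outcome carriers and the manifest are always preserved.
#'
#' @param unfolded Output of [markov_unfold()].
#' @param set_name One of `"MAIN"`, `"ACTIONABLE"`, `"TOP5"`.
#' @param features For `TOP5`: character vector of exact column names.
#' @return Filtered tibble with attributes preserved.
#' @export
select_variable_set <- function(unfolded, set_name = c("MAIN", "ACTIONABLE", "TOP5"),
                                features = NULL) {
  if (!set_name[1] %in% c("MAIN", "ACTIONABLE", "TOP5"))
    stop_config("set_name", "must be one of MAIN, ACTIONABLE, TOP5")
  set_name <- set_name[1]
  manifest <- feature_manifest(unfolded)
  id_cols <- intersect(c("participant_id", "date", "am_prs", "am_prs_c",
                         "hrv_change"), names(unfolded))
  if (set_name == "TOP5") {
    if (is.null(features)) stop_config("features", "must be supplied for TOP5")
    missing_f <- setdiff(features, names(unfolded))
    if (length(missing_f))
      stop_validation(paste("unknown feature(s):", paste(missing_f, collapse = ", ")))
    keep <- union(id_cols, features)
  } else {
    tag <- if (set_name == "MAIN") manifest$main else manifest$actionable
    base_vars <- manifest$variable[tag]
    patt <- paste0("^(", paste(base_vars, collapse = "|"), ")(_lag[0-9]+)?$")
    keep <- union(id_cols, grep(patt, names(unfolded), value = TRUE))
  }
  out <- unfolded[intersect(names(unfolded), keep)]
  attr(out, "manifest") <- manifest
  attr(out, "n_lags") <- attr(unfolded, "n_lags")
  out
}

base_variable <- function(colnames) sub("_lag[0-9]+$", "", colnames)
lag_of <- function(colnames) {
  k <- suppressWarnings(as.integer(sub("^.*_lag([0-9]+)$", "\\1", colnames)))
  ifelse(grepl("_lag[0-9]+$", colnames), k, 0L)
}

#' Assemble an outcome vector and predictor block for modelling
#'
#' Builds a modelling table from an unfolded dataset: an outcome column
#' (`.outcome`) plus the predictor columns of the requested variable set.
#' Same-day leakage is blocked in two ways: columns of variables only
#' measured after the morning observation (training, diet) enter at lags
#' 1+ unless `same_day = "all"`, and same-day copies of the outcome's own
#' measurement family are always excluded (the centered recovery score for
#' the AM PRS outcome; every resting HRV and resting HR column for the HRV
#' change outcome). Logical predictors are converted to 0/1.
#'
#' @param unfolded Output of [markov_unfold()] (optionally already passed
#'   through [select_variable_set()]).
#' @param outcome `"am_prs"` (centered) or `"hrv_change"`.
#' @param variable_set `"MAIN"`, `"ACTIONABLE"` or `"TOP5"`.
#' @param features Exact columns for `TOP5`.
#' @param same_day `"morning_only"` (default) or `"all"` (exploratory:
#'   admit same-day training/diet columns).
#' @return Tibble of class `wc_model_data`: `participant_id`, `date`,
#'   `.outcome`, predictors; attributes `outcome`, `variable_set`,
#'   `manifest`.
#' @export
build_model_data <- function(unfolded, outcome = c("am_prs", "hrv_change"),
                             variable_set = "MAIN", features = NULL,
                             same_day = c("morning_only", "all")) {
  outcome <- match.arg(outcome)
  same_day <- match.arg(same_day)
  manifest <- feature_manifest(unfolded)
  sel <- select_variable_set(unfolded, variable_set, features)

  outcome_col <- if (outcome == "am_prs") "am_prs_c" else "hrv_change"
  if (!outcome_col %in% names(unfolded))
    stop_validation(paste("outcome column", outcome_col, "absent from unfolded data"))

  cand <- setdiff(names(sel), c("participant_id", "date", "am_prs"))
  base <- base_variable(cand)
  lags <- lag_of(cand)
  info <- manifest[match(base, manifest$variable), ]

  drop_family <- if (outcome == "am_prs") "prs" else c("hrv", "hr")
  keep <- rep(TRUE, length(cand))
  keep[lags == 0 & !is.na(info$family) & info$family %in% drop_family] <- FALSE
  if (same_day == "morning_only")
    keep[lags == 0 & !is.na(info$morning) & !info$morning] <- FALSE
  keep[is.na(info$variable)] <- FALSE
  predictors <- cand[keep]

  out <- tibble(
    participant_id = sel$participant_id,
    date = sel$date,
    .outcome = unfolded[[outcome_col]]
  )
  pred_block <- sel[predictors]
  pred_block[] <- lapply(pred_block, function(v) as.numeric(v))
  out <- bind_cols(out, pred_block)
  out <- out[complete.cases(out), ]
  structure(out, class = c("wc_model_data", class(tibble())),
            outcome = outcome, variable_set = variable_set, manifest = manifest)
}

#' Prune correlated predictors of a modelling table
#'
#' Applies [prune_correlated()] to the predictor block of a
#' `wc_model_data` object, once, on the full dataset prior to
#' cross-validation.
#'
#' @param md A [build_model_data()] result.
#' @param threshold Absolute-correlation cutoff.
#' @return `md` with pruned predictors; removed columns recorded in
#'   attribute `"removed"`.
#' @export
prune_model_data <- function(md, threshold = 0.85) {
  pred_cols <- setdiff(names(md), c("participant_id", "date", ".outcome"))
  pr <- prune_correlated(md[pred_cols], threshold)
  out <- bind_cols(md[c("participant_id", "date", ".outcome")], pr$x)
  attributes(out)[c("outcome", "variable_set", "manifest")] <-
    attributes(md)[c("outcome", "variable_set", "manifest")]
  class(out) <- class(md)
  attr(out, "removed") <- pr$removed
  out
}
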