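new_wc_importance <- function(table, method, fit, baseline_rmse = NA_real_,
                              repeats = NULL) {
  structure(list(table = table, method = method, outcome = fit$outcome,
                 level = fit$level, learner = fit$learner,
                 participant_id = fit$participant_id,
                 baseline_rmse = baseline_rmse, repeats = repeats),
            class = "wc_importance")
}

# per-row linear sensitivity b_f / scale_f for the fold (or final) model
# covering each row; NA where no linear fast path exists
linear_row_weights <- function(fit, feature, n) {
  units <- if (!is.null(fit$folds)) fit$folds else
    list(list(record = fit$final_model$record, std = fit$final_model$std,
              test_rows = seq_len(n)))
  if (!all(vapply(units, function(u) u$record$kind == "linear", logical(1))))
    return(NULL)
  w <- rep(NA_real_, n)
  for (u in units) {
    w[u$test_rows] <- u$record$b[[feature]] / u$std$scale[[feature]]
  }
  w
}

# model predictions with (possibly modified) raw predictor matrix
predict_units <- function(fit, x) {
  n <- nrow(x)
  units <- if (!is.null(fit$folds)) fit$folds else
    list(list(record = fit$final_model$record, std = fit$final_model$std,
              test_rows = seq_len(n)))
  pred <- rep(NA_real_, n)
  for (u in units) {
    z <- std_apply(x[u$test_rows, , drop = FALSE], u$std)
    pred[u$test_rows] <- predict_record(u$record, z)
  }
  pred
}

#' Permutation feature importance
#'
#' Importance of a feature is the increase in the model's prediction error
#' after permuting that feature's values, averaged over `n_repeats`
#' independent permutations (the per-repeat distribution is retained for
#' boxplots). For group fits the error is measured on held-out
#' leave-one-subject-out predictions — each row is scored by the fold model
#' that never saw its athlete — for individual fits on the athlete's own
#' rows under the final model. May be negative for uninformative features.
#'
#' @param fit A `wc_fit` from [fit_group_model()] or
#'   [fit_individual_models()].
#' @param data The `wc_model_data` the fit was produced from (same rows).
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed for the permutations.
#' @param features Features to score (default: all predictors of the fit).
#' @return A `wc_importance` object; `$table` has `feature`, `importance`
#'   (mean RMSE increase), `sd`, ranked descending.
#' @export
permutation_importance <- function(fit, data, n_repeats = 10, seed = 1,
                                   features = fit$pred_cols) {
  stopifnot(inherits(fit, "wc_fit"))
  if (n_repeats < 1) stop_config("n_repeats", "must be >= 1")
  missing_f <- setdiff(features, fit$pred_cols)
  if (length(missing_f))
    stop_validation(paste("feature(s) not in model:", paste(missing_f, collapse = ", ")))
  x <- as.matrix(data[fit$pred_cols])
  y <- data$.outcome
  n <- nrow(x)
  base_pred <- if (!is.null(fit$heldout_pred)) fit$heldout_pred else
    predict_units(fit, x)
  rmse0 <- sqrt(mean((y - base_pred)^2, na.rm = TRUE))

  set.seed(child_seed(seed, "permutation"))
  perms <- replicate(n_repeats, sample.int(n), simplify = FALSE)
  res <- matrix(NA_real_, length(features), n_repeats,
                dimnames = list(features, NULL))
  for (f in features) {
    w <- linear_row_weights(fit, f, n)
    for (r in seq_len(n_repeats)) {
      xf_perm <- x[perms[[r]], f]
      if (!is.null(w)) {
        pred <- base_pred + w * (xf_perm - x[, f])
      } else {
        xp <- x
        xp[, f] <- xf_perm
        pred <- predict_units(fit, xp)
      }
      res[f, r] <- sqrt(mean((y - pred)^2, na.rm = TRUE)) - rmse0
    }
  }
  tab <- tibble(feature = features,
                importance = unname(rowMeans(res)),
                sd = unname(apply(res, 1, sd))) |>
    arrange(desc(.data$importance))
  new_wc_importance(tab, "permutation", fit, baseline_rmse = rmse0,
                    repeats = res)
}

#' Model-based importance, scaled to sum to one
#'
#' For linear learners, the absolute standardized coefficients of the final
#' model; for other learners, a permutation-based fallback with negative
#' values truncated at zero. Either way the vector is scaled so total
#' importance sums to 1, which makes importances comparable (and
#' averageable) across athletes whose chosen algorithms differ. If every
#' raw importance is zero a uniform vector is returned with a warning.
#'
#' @param fit A `wc_fit` with a final model.
#' @param data Required for the permutation fallback of non-linear models.
#' @param seed Seed for the fallback permutations.
#' @return A `wc_importance` with method `"model_based_scaled"`; the
#'   importances are nonnegative and sum to 1.
#' @export
model_importance_scaled <- function(fit, data = NULL, seed = 1) {
  stopifnot(inherits(fit, "wc_fit"))
  rec <- fit$final_model$record
  if (rec$kind == "linear") {
    raw <- abs(rec$b)
    feats <- names(raw)
  } else {
    if (is.null(data))
      stop_validation("non-linear model: supply `data` for the permutation fallback")
    pi <- permutation_importance(fit, data, n_repeats = 10, seed = seed)
    raw <- pmax(pi$table$importance, 0)
    feats <- pi$table$feature
  }
  if (sum(raw) == 0) {
    warn("all importances are zero; returning a uniform vector")
    raw <- rep(1, length(raw))
  }
  tab <- tibble(feature = feats, importance = unname(as.numeric(raw / sum(raw)))) |>
    arrange(desc(.data$importance))
  new_wc_importance(tab, "model_based_scaled", fit)
}

#' Average scaled importances across athletes
#'
#' Means the scaled per-athlete importance vectors over a list of reports;
#' a feature absent from an athlete's model counts as 0 for that athlete.
#' Because each input sums to 1, the aggregate reflects the share of
#' predictive weight a feature carries on the average athlete, regardless
#' of which algorithm each athlete's model used.
#'
#' @param reports Non-empty list of `wc_importance` objects (scaled).
#' @return A `wc_importance` with method `"aggregated"`, ranked descending;
#'   `$table$n_models` counts the athletes whose model contained the
#'   feature.
#' @export
aggregate_individual_importance <- function(reports) {
  if (!length(reports)) stop_validation("no importance reports supplied")
  feats <- sort(unique(unlist(lapply(reports, function(r) r$table$feature))))
  mat <- vapply(reports, function(r) {
    v <- setNames(rep(0, length(feats)), feats)
    v[r$table$feature] <- r$table$importance
    v
  }, numeric(length(feats)))
  mat <- matrix(mat, nrow = length(feats), dimnames = list(feats, NULL))
  tab <- tibble(feature = feats,
                importance = unname(rowMeans(mat)),
                sd = unname(apply(mat, 1, sd)),
                n_models = unname(rowSums(vapply(reports, function(r)
                  feats %in% r$table$feature, logical(length(feats)))))) |>
    arrange(desc(.data$importance), .data$feature)
  structure(list(table = tab, method = "aggregated",
                 outcome = reports[[1]]$outcome, level = "individual",
                 learner = "mixed", participant_id = NA_character_,
                 baseline_rmse = NA_real_, repeats = NULL),
            class = "wc_importance")
}

#' Top-k features of an importance report
#'
#' The `k` features with the highest mean importance; ties broken
#' alphabetically so the answer is deterministic.
#'
#' @param report A `wc_importance`.
#' @param k How many features (default 5; must not exceed the number
#'   scored).
#' @return Character vector of feature names.
#' @export
top_k_features <- function(report, k = 5) {
  stopifnot(inherits(report, "wc_importance"))
  if (k > nrow(report$table)) stop_config("k", "exceeds the number of features")
  if (k == 0) return(character(0))
  tab <- report$table |> arrange(desc(.data$importance), .data$feature)
  tab$feature[seq_len(k)]
}

#' Partial-dependence profile of one feature
#'
#' Sweeps a continuous feature over an even grid spanning its 5th to 95th
#' percentile; at each grid value the feature column is set to that value
#' for every observation and the mean model prediction is recorded, which
#' shows how the expected prediction moves with the feature after averaging
#' over the observed values of everything else. Per-observation profiles
#' (ICE curves) can be retained.
#'
#' @param fit A `wc_fit` with a final model (or a [fit_lmm_top5()] result).
#' @param data The modelling table.
#' @param feature Feature column name; must have nonzero variance.
#' @param grid_size Number of grid points (default 20).
#' @param ice Keep per-observation profiles.
#' @return A `wc_pd` object: `feature`, `grid` (strictly increasing),
#'   `profile` (mean prediction per grid value), optional `ice` matrix.
#' @export
partial_dependence <- function(fit, data, feature, grid_size = 20, ice = FALSE) {
  stopifnot(inherits(fit, "wc_fit"))
  if (!feature %in% fit$pred_cols)
    stop_validation(paste("feature not in model:", feature))
  v <- data[[feature]]
  qs <- quantile(v, c(0.05, 0.95), na.rm = TRUE)
  if (diff(qs) <= 0 || sd(v, na.rm = TRUE) == 0)
    stop_validation(paste("zero-variance feature:", feature))
  grid <- seq(qs[1], qs[2], length.out = grid_size)

  use_lmm <- !is.null(fit$final_lmm)
  x <- as.matrix(data[fit$pred_cols])
  profile <- numeric(grid_size)
  ice_mat <- if (ice) matrix(NA_real_, nrow(x), grid_size) else NULL
  for (g in seq_len(grid_size)) {
    if (use_lmm) {
      nd <- data
      nd[[feature]] <- grid[g]
      pred <- predict(fit$final_lmm, newdata = nd, re.form = NA,
                      allow.new.levels = TRUE)
    } else {
      xg <- x
      xg[, feature] <- grid[g]
      pred <- predict_record(fit$final_model$record,
                             std_apply(xg, fit$final_model$std))
    }
    profile[g] <- mean(pred)
    if (ice) ice_mat[, g] <- pred
  }
  structure(list(feature = feature, grid = grid, profile = profile,
                 ice = ice_mat, outcome = fit$outcome, learner = fit$learner),
            class = "wc_pd")
}

#' @export
print.wc_importance <- function(x, ...) {
  cat(sprintf("<wc_importance> %s | %s | %s\n", x$method, x$outcome, x$level))
  print(head(x$table, 10))
  invisible(x)
}

#' @export
print.wc_pd <- function(x, ...) {
  cat(sprintf("<wc_pd> %s (%d grid points), prediction range [%.3f, %.3f]\n",
              x$feature, length(x$grid), min(x$profile), max(x$profile)))
  invisible(x)
}
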