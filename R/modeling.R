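#' Prediction accuracy metrics
#'
#' Root mean squared error in the units of the outcome, and R-squared
#' defined as the squared Pearson correlation between observed and
#' predicted values (0 when the predictions are constant, as for an
#' intercept-only model).
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 values).
#' @return Named list `rmse`, `r_squared`.
#' @export
#' @examples
#' score_predictions(c(0, 0, 4), c(0, 0, 0)) # rmse sqrt(16/3), r2 0
score_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop_validation("observed and predicted must have equal length")
  if (length(observed) < 2)
    stop_validation("need at least 2 values to score")
  rmse <- sqrt(mean((observed - predicted)^2))
  r2 <- if (sd(predicted) == 0 || sd(observed) == 0) 0 else
    cor(observed, predicted)^2
  list(rmse = rmse, r_squared = r2)
}

pred_columns <- function(data, uses_interactions = TRUE) {
  cols <- setdiff(names(data), c("participant_id", "date", ".outcome"))
  if (!uses_interactions) {
    manifest <- attr(data, "manifest")
    ix_vars <- manifest$variable[manifest$interaction]
    cols <- cols[!base_variable(cols) %in% ix_vars]
  }
  cols
}

new_wc_fit <- function(...) {
  structure(list(...), class = "wc_fit")
}

fold_ci <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 2) return(c(NA_real_, NA_real_))
  m <- mean(v); se <- sd(v) / sqrt(length(v))
  m + c(-1, 1) * qt(0.975, length(v) - 1) * se
}

#' Fit a group-level model under leave-one-subject-out cross-validation
#'
#' For each participant in turn, the model is fit on every other
#' participant's rows (hyperparameters tuned by inner cross-validation on
#' that training portion only) and evaluated on the held-out participant,
#' so no test athlete's rows ever touch training. The reported RMSE and
#' R-squared are the across-fold means with t-interval 95% CIs from the
#' fold distribution. Predictors are standardized using training-fold
#' means/SDs before penalized fits. A final model tuned on the full dataset
#' is kept for interpretation (partial dependence).
#'
#' @param data A pruned [build_model_data()] table with >= 3 participants.
#' @param learner Learner name, see [learner_spec()]. Unavailable learners
#'   are skipped with a warning (returns `NULL`).
#' @param inner_folds Folds of the inner tuning CV (default 5).
#' @param nlambda Length of the glmnet penalty path.
#' @param seed Integer seed governing fold assignment and tuning.
#' @return A `wc_fit` object: identity (outcome, level, variable set,
#'   learner), `rmse` / `r_squared` with 95% CIs, per-fold `metrics`,
#'   per-fold fitted records (for held-out importance), held-out
#'   predictions, and the final full-data model.
#' @export
fit_group_model <- function(data, learner = "lasso", inner_folds = 5,
                            nlambda = 50, seed = 1) {
  stopifnot(inherits(data, "wc_model_data"))
  spec <- learner_spec(learner)
  if (!spec$available) {
    warn(paste("learner", learner, "is unavailable; skipping"))
    return(NULL)
  }
  parts <- unique(data$participant_id)
  if (length(parts) < 3) stop_validation("group models need >= 3 participants")

  cols <- pred_columns(data, spec$uses_interactions)
  x <- as.matrix(data[cols])
  y <- data$.outcome
  pid <- data$participant_id

  folds <- vector("list", length(parts))
  metrics <- vector("list", length(parts))
  heldout <- rep(NA_real_, length(y))
  for (i in seq_along(parts)) {
    p <- parts[i]
    tr <- pid != p
    st <- std_fit(x[tr, , drop = FALSE])
    ztr <- std_apply(x[tr, , drop = FALSE], st)
    zte <- std_apply(x[!tr, , drop = FALSE], st)
    rec <- tryCatch(
      fit_learner(learner, ztr, y[tr], NULL, inner_folds, nlambda,
                  seed = child_seed(seed, "tuning") + i),
      error = function(e) e)
    if (inherits(rec, "error")) {
      warn(sprintf("fold %s failed (%s); excluded", p, conditionMessage(rec)))
      next
    }
    pr <- predict_record(rec, zte)
    heldout[!tr] <- pr
    sc <- score_predictions(y[!tr], pr)
    metrics[[i]] <- tibble(participant_id = p, rmse = sc$rmse,
                           r_squared = sc$r_squared, n_test = sum(!tr))
    folds[[i]] <- list(participant_id = p, record = rec, std = st,
                       test_rows = which(!tr))
  }
  metrics <- bind_rows(metrics)
  if (nrow(metrics) == 0) stop_validation("all LOSO folds failed")

  st_all <- std_fit(x)
  final <- fit_learner(learner, std_apply(x, st_all), y, NULL, inner_folds,
                       nlambda, seed = child_seed(seed, "tuning"))

  new_wc_fit(
    outcome = attr(data, "outcome"), level = "group",
    variable_set = attr(data, "variable_set"), learner = learner,
    participant_id = NA_character_,
    rmse = mean(metrics$rmse), rmse_ci = fold_ci(metrics$rmse),
    r_squared = mean(metrics$r_squared), r2_ci = fold_ci(metrics$r_squared),
    metrics = metrics, hyper = final$hyper,
    pred_cols = cols, folds = Filter(Negate(is.null), folds),
    heldout_pred = heldout, data_outcome = y,
    final_model = list(record = final, std = st_all)
  )
}

#' Intercept-only baseline under leave-one-subject-out cross-validation
#'
#' The constant predictor: each held-out participant is predicted with the
#' training-fold outcome mean. Its LOSO RMSE approximates the outcome SD
#' and sets the bar any useful model must beat; R-squared is 0 by the
#' constant-prediction convention.
#'
#' @inheritParams fit_group_model
#' @return A `wc_fit` object with learner `"intercept"`.
#' @export
fit_baseline <- function(data, seed = 1) {
  fit <- fit_group_model(data, learner = "intercept", seed = seed)
  fit$r_squared <- 0
  fit$r2_ci <- c(0, 0)
  fit
}

#' Linear mixed model on the top-five features
#'
#' Random-intercept linear mixed model with the supplied features (normally
#' the five highest-importance variables of the group MAIN model) as fixed
#' effects and participant as a random effect, evaluated under the same
#' leave-one-subject-out scheme as the other group models: the held-out
#' athlete's random effect is unknown and set to zero at prediction time.
#'
#' @param data A [build_model_data()] table.
#' @param features Character vector of (lagged) feature column names;
#'   fitting proceeds with fewer than five, with a warning.
#' @param seed Integer seed (kept for interface symmetry; the fit is
#'   deterministic).
#' @return A `wc_fit` with learner `"lmm"`, including the final full-data
#'   `lme4` fit in `$final_lmm`.
#' @export
fit_lmm_top5 <- function(data, features, seed = 1) {
  stopifnot(inherits(data, "wc_model_data"))
  missing_f <- setdiff(features, names(data))
  if (length(missing_f))
    stop_validation(paste("feature(s) not in data:", paste(missing_f, collapse = ", ")))
  if (length(features) < 5)
    warn(sprintf("only %d feature(s) supplied; fitting with what is given",
                 length(features)))
  fml <- as.formula(paste(".outcome ~", paste(features, collapse = " + "),
                          "+ (1 | participant_id)"))
  parts <- unique(data$participant_id)
  metrics <- vector("list", length(parts))
  heldout <- rep(NA_real_, nrow(data))
  for (i in seq_along(parts)) {
    p <- parts[i]
    tr <- data$participant_id != p
    fit <- tryCatch(
      suppressMessages(lme4::lmer(fml, data = data[tr, ], REML = TRUE)),
      error = function(e) {
        stop_validation(paste("mixed model failed to converge:",
                              conditionMessage(e)))
      })
    pr <- predict(fit, newdata = data[!tr, ], re.form = NA,
                  allow.new.levels = TRUE)
    heldout[!tr] <- pr
    sc <- score_predictions(data$.outcome[!tr], pr)
    metrics[[i]] <- tibble(participant_id = p, rmse = sc$rmse,
                           r_squared = sc$r_squared, n_test = sum(!tr))
  }
  metrics <- bind_rows(metrics)
  final <- suppressMessages(lme4::lmer(fml, data = data, REML = TRUE))

  new_wc_fit(
    outcome = attr(data, "outcome"), level = "group",
    variable_set = "TOP5", learner = "lmm", participant_id = NA_character_,
    rmse = mean(metrics$rmse), rmse_ci = fold_ci(metrics$rmse),
    r_squared = mean(metrics$r_squared), r2_ci = fold_ci(metrics$r_squared),
    metrics = metrics, hyper = list(features = features),
    pred_cols = features, folds = NULL,
    heldout_pred = heldout, data_outcome = data$.outcome,
    final_lmm = final
  )
}

#' Bootstrap accuracy metrics for one model on one athlete's data
#'
#' Refits the model on each bootstrap resample of the rows and evaluates
#' RMSE and R-squared on the out-of-bag rows; resamples with no out-of-bag
#' rows are redrawn. Reported as the distribution over resamples.
#'
#' @param x Numeric predictor matrix (possibly 0 columns for the intercept
#'   model).
#' @param y Outcome vector.
#' @param fit_fun `function(x, y)` returning a prediction
#'   `function(xnew)`.
#' @param B Number of resamples (>= 2; default 500).
#' @param seed Integer seed; resample indices are reproducible.
#' @return Tibble with one row per resample: `resample`, `rmse`,
#'   `r_squared`, `n_oob`.
#' @export
bootstrap_metrics <- function(x, y, fit_fun, B = 500, seed = 1) {
  if (B < 2) stop_config("B", "must be >= 2")
  set.seed(seed)
  n <- length(y)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob) >= 2) break
    }
    pred_fun <- fit_fun(x[idx, , drop = FALSE], y[idx])
    sc <- score_predictions(y[oob], pred_fun(x[oob, , drop = FALSE]))
    out[[b]] <- tibble(resample = b, rmse = sc$rmse,
                       r_squared = sc$r_squared, n_oob = length(oob))
  }
  bind_rows(out)
}

# repeated k-fold CV RMSE for one learner on one athlete's data;
# returns list(rmse, hyper)
repeated_cv_rmse <- function(name, x, y, cv_folds, cv_repeats, seed) {
  n <- length(y)
  k <- min(cv_folds, max(2, n %/% 3))
  if (name %in% c("ridge", "lasso", "lasso_interactions")) {
    alpha <- if (name == "ridge") 0 else 1
    st <- std_fit(x); z <- std_apply(x, st)
    master <- glmnet::glmnet(z, y, alpha = alpha, nlambda = 30,
                             standardize = FALSE)
    lam <- master$lambda
    cvm <- matrix(NA_real_, cv_repeats, length(lam))
    for (r in seq_len(cv_repeats)) {
      foldid <- make_foldid(n, k, seed + r)
      cv <- glmnet::cv.glmnet(z, y, alpha = alpha, lambda = lam,
                              foldid = foldid, standardize = FALSE)
      cvm[r, seq_along(cv$cvm)] <- cv$cvm
    }
    m <- colMeans(cvm)
    best <- which.min(m)
    list(rmse = sqrt(m[best]), hyper = list(lambda = lam[best], alpha = alpha))
  } else {
    spec <- learner_spec(name)
    errs <- c()
    best_hyper <- NULL
    for (r in seq_len(cv_repeats)) {
      foldid <- make_foldid(n, k, seed + r)
      for (f in unique(foldid)) {
        tr <- foldid != f
        st <- std_fit(x[tr, , drop = FALSE])
        rec <- fit_learner(name, std_apply(x[tr, , drop = FALSE], st), y[tr],
                           best_hyper, inner_folds = 3,
                           seed = seed + r * 100 + f)
        if (is.null(best_hyper)) best_hyper <- rec$hyper
        pr <- predict_record(rec, std_apply(x[!tr, , drop = FALSE], st))
        errs <- c(errs, y[!tr] - pr)
      }
    }
    list(rmse = sqrt(mean(errs^2)), hyper = best_hyper)
  }
}

#' Fit individualized models, one per athlete
#'
#' For each participant with at least `min_rows` usable rows: every
#' requested (available) learner and its hyperparameter grid is evaluated
#' by `cv_repeats` x `cv_folds`-fold cross-validation on that athlete's
#' rows only; the learner/parameter pair with the lowest mean CV RMSE is
#' chosen, ties going to the simpler learner class (regularized linear
#' first). Final accuracy metrics come from [bootstrap_metrics()] with `B`
#' out-of-bag resamples, reported as mean and SD. Runs are deterministic
#' given `seed`.
#'
#' @param data A pruned [build_model_data()] table.
#' @param learners Learner names to consider (default the native trio
#'   lasso / ridge / knn).
#' @param cv_folds,cv_repeats Cross-validation geometry (default 10 x 10).
#' @param min_rows Minimum usable rows per athlete (default 30); athletes
#'   below it are skipped with a warning.
#' @param B Bootstrap resamples for the final metrics (default 500).
#' @param seed Integer seed fanned out per athlete.
#' @return Named list of `wc_fit` objects (one per fitted athlete), each
#'   with `level = "individual"`, the chosen learner and hyperparameters,
#'   bootstrap `metrics`, and the final model for interpretation.
#' @export
fit_individual_models <- function(data, learners = c("lasso", "ridge", "knn"),
                                  cv_folds = 10, cv_repeats = 10,
                                  min_rows = 30, B = 500, seed = 1) {
  stopifnot(inherits(data, "wc_model_data"))
  specs <- lapply(learners, learner_spec)
  avail <- vapply(specs, `[[`, logical(1), "available")
  if (any(!avail))
    warn(paste("unavailable learner(s) skipped:",
               paste(learners[!avail], collapse = ", ")))
  specs <- specs[avail]
  if (!length(specs)) stop_validation("no available learners requested")

  parts <- unique(data$participant_id)
  fits <- list()
  for (i in seq_along(parts)) {
    p <- parts[i]
    d <- data[data$participant_id == p, ]
    if (nrow(d) < min_rows) {
      warn(sprintf("participant %s skipped: only %d rows (< %d)", p, nrow(d), min_rows))
      next
    }
    y <- d$.outcome
    pseed <- child_seed(seed, "folds") + i
    cand <- lapply(specs, function(sp) {
      xs <- as.matrix(d[pred_columns(data, sp$uses_interactions)])
      cv <- repeated_cv_rmse(sp$name, xs, y, cv_folds, cv_repeats, pseed)
      list(spec = sp, x = xs, rmse = cv$rmse, hyper = cv$hyper)
    })
    rmses <- vapply(cand, `[[`, numeric(1), "rmse")
    ranks <- vapply(cand, function(cc) cc$spec$rank, numeric(1))
    best <- cand[[order(rmses, ranks)[1]]]

    st <- std_fit(best$x)
    final <- fit_learner(best$spec$name, std_apply(best$x, st), y, best$hyper,
                         seed = pseed)
    boot <- bootstrap_metrics(
      best$x, y,
      function(xb, yb) {
        stb <- std_fit(xb)
        rec <- fit_learner(best$spec$name, std_apply(xb, stb), yb, best$hyper,
                           seed = pseed)
        function(xnew) predict_record(rec, std_apply(xnew, stb))
      },
      B = B, seed = child_seed(seed, "bootstrap") + i)

    fits[[p]] <- new_wc_fit(
      outcome = attr(data, "outcome"), level = "individual",
      variable_set = attr(data, "variable_set"), learner = best$spec$name,
      participant_id = p,
      rmse = mean(boot$rmse), rmse_sd = sd(boot$rmse),
      rmse_ci = unname(quantile(boot$rmse, c(0.025, 0.975))),
      r_squared = mean(boot$r_squared), r2_sd = sd(boot$r_squared),
      r2_ci = unname(quantile(boot$r_squared, c(0.025, 0.975))),
      metrics = boot, hyper = best$hyper, cv_rmse = best$rmse,
      pred_cols = colnames(best$x), folds = NULL,
      final_model = list(record = final, std = st)
    )
  }
  fits
}

#' Per-athlete linear models on a fixed small feature set
#'
#' Fits an ordinary linear model per athlete using the supplied features —
#' either one shared vector (e.g. the top five of the group MAIN model) or
#' a named list giving each athlete their own five — with accuracy from
#' out-of-bag bootstrap resamples. An empty feature set yields the
#' athlete's intercept-only baseline.
#'
#' @param data A [build_model_data()] table.
#' @param features Character vector, or named list of vectors keyed by
#'   participant id.
#' @param label Variable-set label stored on the results (e.g.
#'   `"top5_group"`, `"top5_individual"`, `"baseline"`).
#' @param min_rows Minimum rows per athlete.
#' @param B,seed Bootstrap size and seed.
#' @return Named list of `wc_fit` objects with learner `"linear"` (or
#'   `"intercept"` when `features` is empty).
#' @export
fit_individual_linear <- function(data, features, label = "top5",
                                  min_rows = 30, B = 500, seed = 1) {
  stopifnot(inherits(data, "wc_model_data"))
  parts <- unique(data$participant_id)
  fits <- list()
  for (i in seq_along(parts)) {
    p <- parts[i]
    feats <- if (is.list(features)) features[[p]] else features
    if (is.null(feats)) next
    d <- data[data$participant_id == p, ]
    if (nrow(d) < min_rows) next
    missing_f <- setdiff(feats, names(d))
    if (length(missing_f))
      stop_validation(paste("feature(s) not in data:", paste(missing_f, collapse = ", ")))
    y <- d$.outcome
    x <- as.matrix(d[feats])
    if (!length(feats)) x <- matrix(numeric(0), nrow = nrow(d), ncol = 0)
    lname <- if (length(feats)) "linear" else "intercept"
    st <- if (length(feats)) std_fit(x) else list(center = numeric(0), scale = numeric(0))
    zfun <- function(xx, stt) if (ncol(xx)) std_apply(xx, stt) else xx
    final <- fit_learner(lname, zfun(x, st), y, seed = seed)
    boot <- bootstrap_metrics(
      x, y,
      function(xb, yb) {
        stb <- if (ncol(xb)) std_fit(xb) else st
        rec <- fit_learner(lname, zfun(xb, stb), yb, seed = seed)
        function(xnew) predict_record(rec, zfun(xnew, stb))
      },
      B = B, seed = child_seed(seed, "bootstrap") + i)
    r2 <- if (lname == "intercept") 0 else mean(boot$r_squared)
    fits[[p]] <- new_wc_fit(
      outcome = attr(data, "outcome"), level = "individual",
      variable_set = label, learner = lname, participant_id = p,
      rmse = mean(boot$rmse), rmse_sd = sd(boot$rmse),
      rmse_ci = unname(quantile(boot$rmse, c(0.025, 0.975))),
      r_squared = r2, r2_sd = sd(boot$r_squared),
      r2_ci = unname(quantile(boot$r_squared, c(0.025, 0.975))),
      metrics = boot, hyper = list(features = feats),
      pred_cols = feats, folds = NULL,
      final_model = list(record = final, std = st)
    )
  }
  fits
}

#' @export
print.wc_fit <- function(x, ...) {
  cat(sprintf("<wc_fit> %s | %s | %s | %s%s\n", x$outcome, x$level,
              x$variable_set, x$learner,
              if (!is.na(x$participant_id)) paste0(" | ", x$participant_id) else ""))
  cat(sprintf("  RMSE %.3f [%.3f, %.3f]  R^2 %.3f\n", x$rmse,
              x$rmse_ci[1], x$rmse_ci[2], x$r_squared))
  invisible(x)
}
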