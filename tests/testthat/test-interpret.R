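make_linear_group_fit <- function(beta = c(3, 0), noise_sd = 0.1, n = 300,
                                  seed = 2) {
  set.seed(seed)
  df <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:6), each = n / 6),
    date = rep(as.Date("2024-01-01") + 1:(n / 6), 6),
    x1 = rnorm(n), x2 = rnorm(n))
  df$.outcome <- beta[1] * df$x1 + beta[2] * df$x2 + rnorm(n, 0, noise_sd)
  md <- make_md(df)
  list(md = md, fit = fit_group_model(md, "linear", seed = 1))
}

test_that("permutation importance separates signal from null features", {
  obj <- make_linear_group_fit(beta = c(3, 0), noise_sd = 0.5)
  imp <- permutation_importance(obj$fit, obj$md, n_repeats = 20)
  tab <- imp$table
  i1 <- tab$importance[tab$feature == "x1"]
  i2 <- tab$importance[tab$feature == "x2"]
  s2 <- tab$sd[tab$feature == "x2"]
  expect_gt(i1, 0)
  # null feature: importance negligible next to the signal feature
  expect_lt(abs(i2), 0.02 * i1)
  expect_lt(abs(i2), 6 * s2 / sqrt(20) + 1e-3)
  # analytic check: noise-free permuted RMSE tends to sqrt(2) * sd(3 x)
  obj0 <- make_linear_group_fit(beta = c(3, 0), noise_sd = 1e-6, n = 3000)
  imp0 <- permutation_importance(obj0$fit, obj0$md, n_repeats = 10)
  perm_rmse <- imp0$table$importance[imp0$table$feature == "x1"] +
    imp0$baseline_rmse
  expect_equal(unname(perm_rmse), sqrt(2) * sd(3 * obj0$md$x1), tolerance = 0.05)
  expect_error(permutation_importance(obj$fit, obj$md, features = "zz"),
               class = "wellcast_validation_error")
})

test_that("a lasso-zeroed feature has exactly zero importance and a flat profile", {
  set.seed(4)
  n <- 400
  df <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:4), each = n / 4),
    date = rep(as.Date("2024-01-01") + 1:(n / 4), 4),
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$.outcome <- 4 * df$x1 + rnorm(n, 0, 0.3)
  md <- make_md(df)
  fit <- fit_group_model(md, "lasso", inner_folds = 3, nlambda = 30)
  zeroed <- names(which(vapply(fit$folds, function(u) u$record$b[["x3"]] == 0,
                               logical(1))))
  imp <- permutation_importance(fit, md, n_repeats = 5)
  if (all(vapply(fit$folds, function(u) u$record$b[["x3"]] == 0, logical(1)))) {
    expect_equal(imp$table$importance[imp$table$feature == "x3"], 0)
  }
  pd <- partial_dependence(fit, md, "x3")
  if (fit$final_model$record$b[["x3"]] == 0) {
    expect_equal(diff(range(pd$profile)), 0)
  }
})

test_that("duplicated features split importance; joint permutation exceeds individual", {
  set.seed(19)
  n <- 400
  df <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:4), each = n / 4),
    date = rep(as.Date("2024-01-01") + 1:(n / 4), 4),
    x1 = rnorm(n))
  df$x1b <- df$x1 + rnorm(n, 0, 0.01)
  df$.outcome <- 3 * df$x1 + rnorm(n, 0, 0.2)
  md <- make_md(df)
  fit <- fit_group_model(md, "ridge", inner_folds = 3, nlambda = 30)
  imp <- permutation_importance(fit, md, n_repeats = 10)
  indiv_max <- max(imp$table$importance)
  # joint permutation: permute both copies together
  x <- as.matrix(md[fit$pred_cols]); y <- md$.outcome
  set.seed(1)
  joint <- replicate(10, {
    idx <- sample.int(nrow(x))
    xp <- x; xp[, c("x1", "x1b")] <- x[idx, c("x1", "x1b")]
    sqrt(mean((y - wellcast:::predict_units(fit, xp))^2)) - imp$baseline_rmse
  })
  expect_gt(mean(joint), indiv_max)
})

test_that("scaled model-based importance is a proper weight vector", {
  obj <- make_linear_group_fit(beta = c(2, 0), noise_sd = 0.2)
  sc <- model_importance_scaled(obj$fit)
  expect_equal(sum(sc$table$importance), 1, tolerance = 1e-8)
  expect_true(all(sc$table$importance >= 0))
  # single nonzero coefficient concentrates all weight
  expect_gt(sc$table$importance[sc$table$feature == "x1"], 0.95)

  # two equal standardized coefficients split it evenly
  obj2 <- make_linear_group_fit(beta = c(2, 2), noise_sd = 0.05)
  sc2 <- model_importance_scaled(obj2$fit)
  expect_equal(sort(sc2$table$importance), c(0.5, 0.5), tolerance = 0.05)
})

test_that("aggregation across athletes averages scaled importances", {
  obj <- make_linear_group_fit()
  sc <- model_importance_scaled(obj$fit)
  agg_same <- aggregate_individual_importance(list(sc, sc, sc))
  expect_equal(agg_same$table$importance[agg_same$table$feature == "x1"],
               sc$table$importance[sc$table$feature == "x1"], tolerance = 1e-12)

  r1 <- sc; r1$table <- tibble::tibble(feature = "a", importance = 1)
  r2 <- sc; r2$table <- tibble::tibble(feature = "b", importance = 1)
  agg <- aggregate_individual_importance(list(r1, r2))
  expect_equal(agg$table$importance, c(0.5, 0.5))
  expect_error(aggregate_individual_importance(list()),
               class = "wellcast_validation_error")
})

test_that("individual importance is more diffuse than group importance under heterogeneity", {
  cfg <- cohort_config(n_participants = 8, n_days = 56, missing_rate = 0,
                       heterogeneity_sd = 2.5, seed = 88)
  prep <- prep_cohort(cfg)
  md <- prune_model_data(build_model_data(prep$unfolded, "am_prs", "MAIN"))
  g <- fit_group_model(md, "lasso", inner_folds = 3, nlambda = 20)
  g_imp <- model_importance_scaled(g)
  ind <- fit_individual_models(md, learners = "lasso", cv_folds = 5,
                               cv_repeats = 2, B = 20, seed = 3)
  agg <- suppressWarnings(aggregate_individual_importance(
    lapply(ind, model_importance_scaled, data = md)))
  entropy <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  expect_gt(entropy(agg$table$importance), entropy(g_imp$table$importance))
})

test_that("partial dependence of a linear model is its coefficient", {
  set.seed(6)
  n <- 200
  df <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:4), each = n / 4),
    date = rep(as.Date("2024-01-01") + 1:(n / 4), 4),
    x1 = rnorm(n, 0, 2), x2 = rnorm(n))
  df$.outcome <- 1.7 * df$x1 - 0.8 * df$x2 + rnorm(n, 0, 0.1)
  md <- make_md(df)
  fit <- fit_group_model(md, "linear", seed = 1)
  pd <- partial_dependence(fit, md, "x1", grid_size = 15)
  expect_true(all(diff(pd$grid) > 0))
  expect_equal(length(pd$profile), 15)
  slopes <- diff(pd$profile) / diff(pd$grid)
  b_raw <- fit$final_model$record$b[["x1"]] / fit$final_model$std$scale[["x1"]]
  expect_equal(unname(slopes), rep(unname(b_raw), 14), tolerance = 1e-6)

  # additive model: each profile matches its marginal component up to a constant
  pd2 <- partial_dependence(fit, md, "x2", grid_size = 10)
  b2 <- fit$final_model$record$b[["x2"]] / fit$final_model$std$scale[["x2"]]
  expect_equal(diff(pd2$profile), b2 * diff(pd2$grid), tolerance = 1e-6)

  # baseline model: flat everywhere
  base <- fit_baseline(md)
  pdb <- partial_dependence(base, md, "x1")
  expect_equal(diff(range(pdb$profile)), 0)

  df$const <- 1
  mdc <- make_md(df)
  fitc <- fit_group_model(mdc, "linear", seed = 1)
  expect_error(partial_dependence(fitc, mdc, "const"),
               class = "wellcast_validation_error")
})

test_that("top-k selection is a deterministic sort", {
  rep_tab <- structure(list(table = tibble::tibble(
    feature = c("b", "a", "c", "d"),
    importance = c(0.4, 0.4, 0.15, 0.05))), class = "wc_importance")
  expect_equal(top_k_features(rep_tab, 0), character(0))
  expect_equal(top_k_features(rep_tab, 4), c("a", "b", "c", "d"))
  expect_equal(top_k_features(rep_tab, 2), c("a", "b")) # tie broken alphabetically
  expect_error(top_k_features(rep_tab, 5), class = "wellcast_config_error")
  set.seed(1)
  tab <- tibble::tibble(feature = paste0("f", 1:20), importance = runif(20))
  rep2 <- structure(list(table = tab), class = "wc_importance")
  expect_equal(top_k_features(rep2, 7),
               tab$feature[order(-tab$importance)][1:7])
})
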