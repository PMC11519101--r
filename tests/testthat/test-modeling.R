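test_that("prediction scoring follows the RMSE / squared-correlation definitions", {
  expect_equal(score_predictions(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, r_squared = 1))
  expect_equal(score_predictions(c(0, 0, 4), c(0, 0, 0))$rmse, sqrt(16 / 3))
  expect_equal(score_predictions(c(1, 2, 3), c(2, 2, 2))$r_squared, 0)
  expect_error(score_predictions(1:3, 1:4), class = "wellcast_validation_error")
})

test_that("the intercept baseline predicts each fold's training mean", {
  md <- small_md("am_prs")
  base <- fit_baseline(md)
  expect_equal(base$r_squared, 0)
  for (p in unique(md$participant_id)[1:3]) {
    rows <- md$participant_id == p
    expect_equal(unique(base$heldout_pred[rows]),
                 mean(md$.outcome[!rows]), tolerance = 1e-12)
  }
  # centered outcome, near-balanced folds: baseline RMSE tracks outcome SD
  expect_equal(base$rmse, sd(md$.outcome), tolerance = 0.05 * sd(md$.outcome))
  # LOSO fold count equals the number of participants
  expect_equal(nrow(base$metrics), dplyr::n_distinct(md$participant_id))
})

test_that("an unpenalized lasso matches the closed-form least-squares fit", {
  set.seed(5)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- x %*% c(2, -1, 0.5, 0) + rnorm(n, 0, 0.2)
  z <- scale(x)
  rec <- wellcast:::fit_glmnet(z, as.numeric(y), alpha = 1,
                               hyper = list(lambda = 1e-8),
                               inner_folds = 3, nlambda = 30, seed = 1)
  ols <- coef(lm(y ~ z))
  expect_equal(unname(rec$b), unname(ols[-1]), tolerance = 1e-4)
  expect_equal(as.numeric(rec$a), unname(ols[1]), tolerance = 1e-4)
})

test_that("lasso regularization path is monotone in the penalty", {
  set.seed(6)
  n <- 150
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- as.numeric(x %*% c(3, -2, 1, rep(0, 7)) + rnorm(n))
  z <- scale(x)
  lambdas <- c(0.001, 0.01, 0.1, 0.5, 1, 3)
  nz <- numeric(0); train_rmse <- numeric(0)
  for (lam in lambdas) {
    rec <- wellcast:::fit_glmnet(z, y, 1, list(lambda = lam), 3, 30, 1)
    nz <- c(nz, sum(rec$b != 0))
    train_rmse <- c(train_rmse,
                    sqrt(mean((y - wellcast:::predict_record(rec, z))^2)))
  }
  expect_true(all(diff(nz) <= 0))
  expect_true(all(diff(train_rmse) >= -1e-8))
})

test_that("a group lasso with real signal beats the baseline; leakage guard holds", {
  md <- small_md("am_prs")
  base <- fit_baseline(md)
  g <- fit_group_model(md, "lasso", inner_folds = 3, nlambda = 20)
  expect_lt(g$rmse, base$rmse)
  expect_true(g$r_squared > 0 && g$r_squared <= 1)
  expect_equal(nrow(g$metrics), dplyr::n_distinct(md$participant_id))

  # permuting the outcome destroys the advantage
  md_perm <- md
  set.seed(8)
  md_perm$.outcome <- sample(md_perm$.outcome)
  g_perm <- fit_group_model(md_perm, "lasso", inner_folds = 3, nlambda = 20)
  b_perm <- fit_baseline(md_perm)
  expect_gt(g_perm$rmse, 0.97 * b_perm$rmse)
})

test_that("lasso recovers the generative support at the CV-chosen penalty", {
  # parameter recovery: selected set contains the true support
  set.seed(31)
  hits <- 0
  for (r in 1:10) {
    n <- 400
    x <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("x", 1:15)))
    y <- as.numeric(x %*% c(2, -1.5, 1, rep(0, 12)) + rnorm(n))
    rec <- wellcast:::fit_glmnet(scale(x), y, 1, NULL, 5, 50, seed = r)
    if (all(rec$b[1:3] != 0)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the top-five mixed model degenerates to least squares without grouping structure", {
  set.seed(9)
  n <- 240
  df <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:6), each = n / 6),
    date = rep(as.Date("2024-01-01") + 1:(n / 6), 6),
    x1 = rnorm(n), x2 = rnorm(n))
  df$.outcome <- 2 * df$x1 - df$x2 + rnorm(n, 0, 0.5) # no participant effect
  md <- make_md(df)
  fit <- suppressWarnings(fit_lmm_top5(md, c("x1", "x2")))
  ols <- coef(lm(.outcome ~ x1 + x2, data = df))
  expect_equal(unname(lme4::fixef(fit$final_lmm)), unname(ols), tolerance = 1e-2)
  expect_warning(fit_lmm_top5(md, c("x1", "x2")), "fewer than 5|only")
  expect_error(fit_lmm_top5(md, "missing_col"), class = "wellcast_validation_error")
})

test_that("the top-five mixed model sits between full model and baseline on real signal", {
  md <- small_md("am_prs")
  g <- fit_group_model(md, "lasso", inner_folds = 3, nlambda = 20)
  imp <- permutation_importance(g, md, n_repeats = 5)
  t5 <- top_k_features(imp, 5)
  lmm <- suppressMessages(fit_lmm_top5(md, t5))
  base <- fit_baseline(md)
  expect_lt(lmm$rmse, base$rmse)
})

test_that("individual model selection is deterministic and honest under noise", {
  md <- small_md("am_prs")
  sub <- md[md$participant_id %in% unique(md$participant_id)[1:3], ]
  attributes(sub)[c("outcome", "variable_set", "manifest")] <-
    attributes(md)[c("outcome", "variable_set", "manifest")]
  class(sub) <- class(md)

  f1 <- fit_individual_models(sub, learners = "lasso", cv_folds = 5,
                              cv_repeats = 2, B = 40, seed = 4)
  f2 <- fit_individual_models(sub, learners = "lasso", cv_folds = 5,
                              cv_repeats = 2, B = 40, seed = 4)
  expect_equal(names(f1), names(f2))
  for (p in names(f1)) {
    expect_identical(f1[[p]]$learner, f2[[p]]$learner)
    expect_identical(f1[[p]]$hyper, f2[[p]]$hyper)
    expect_equal(f1[[p]]$rmse, f2[[p]]$rmse, tolerance = 1e-12)
  }

  # pure-noise outcome: chosen model gains nothing over the intercept
  noise <- sub
  set.seed(12)
  noise$.outcome <- rnorm(nrow(noise), 0, 10)
  fn <- fit_individual_models(noise, learners = "lasso", cv_folds = 5,
                              cv_repeats = 2, B = 60, seed = 4)
  for (p in names(fn)) {
    own <- noise$.outcome[noise$participant_id == p]
    expect_lt(abs(fn[[p]]$rmse - sd(own)), 0.2 * sd(own))
  }
})

test_that("a strong personal sleep effect surfaces in that athlete's importance", {
  es <- null_effect_sizes()
  es$prs_sleep_quality <- 8
  cfg <- cohort_config(n_participants = 4, n_days = 60, missing_rate = 0,
                       effect_sizes = es, noise_sd_prs = 6, seed = 77)
  prep <- prep_cohort(cfg)
  md <- prune_model_data(build_model_data(prep$unfolded, "am_prs", "MAIN"))
  fits <- fit_individual_models(md, learners = "lasso", cv_folds = 5,
                                cv_repeats = 2, B = 40, seed = 2)
  hits <- vapply(fits, function(f) {
    top <- top_k_features(model_importance_scaled(f), 1)
    sub("_lag[0-9]+$", "", top) %in%
      c("sleep_quality", "sleep_index", "sleep_index_ma7", "sleep_h")
  }, logical(1))
  expect_gte(sum(hits), length(fits) - 1)
})

test_that("bootstrap metrics behave at the perfect-fit and stochastic extremes", {
  set.seed(14)
  n <- 60
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y_exact <- as.numeric(x %*% c(1, 2))
  fit_fun <- function(xb, yb) {
    rec <- wellcast:::fit_learner("linear", xb, yb)
    function(xnew) wellcast:::predict_record(rec, xnew)
  }
  bo <- bootstrap_metrics(x, y_exact, fit_fun, B = 30, seed = 3)
  expect_true(all(bo$rmse < 1e-8))

  y_noisy <- y_exact + rnorm(n)
  b1 <- bootstrap_metrics(x, y_noisy, fit_fun, B = 50, seed = 5)
  b2 <- bootstrap_metrics(x, y_noisy, fit_fun, B = 50, seed = 5)
  expect_gt(sd(b1$rmse), 0)
  expect_identical(b1, b2)
  expect_error(bootstrap_metrics(x, y_noisy, fit_fun, B = 1),
               class = "wellcast_config_error")
})

test_that("unavailable learners are skipped with a warning", {
  md <- small_md("am_prs")
  expect_warning(res <- fit_group_model(md, "mars"), "unavailable")
  expect_null(res)
  expect_false(learner_spec("gbdt_b")$available)
  expect_error(learner_spec("quantum"), class = "wellcast_config_error")
})
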