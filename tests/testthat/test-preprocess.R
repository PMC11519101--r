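test_that("inclusion rules retain and exclude with reason codes", {
  cohort <- generate_cohort(cohort_config(n_participants = 5, n_days = 50,
                                          missing_rate = 0, seed = 21))
  sessions <- cohort$sessions
  daily <- cohort$daily
  # P01: cut training volume to ~4 h/week
  sessions <- sessions |>
    dplyr::mutate(duration_min = ifelse(participant_id == "P01",
                                        duration_min * 0.3, duration_min))
  # P02: blank 30% of wellness fields
  set.seed(1)
  for (col in c("sleep_h", "soreness", "life_stress", "kcal_per_kg")) {
    idx <- which(daily$participant_id == "P02")
    daily[[col]][sample(idx, length(idx) * 0.9)] <- NA
  }
  # P03: only 30 days of tracking
  daily <- daily |> dplyr::filter(!(participant_id == "P03" & date > min(date) + 29))
  sessions <- sessions |> dplyr::filter(!(participant_id == "P03" & date > min(daily$date) + 29))

  res <- apply_inclusion_rules(sessions, daily)
  rep <- res$report
  expect_false(rep$included[rep$participant_id == "P01"])
  expect_match(rep$reasons[rep$participant_id == "P01"], "low_volume")
  expect_false(rep$included[rep$participant_id == "P02"])
  expect_match(rep$reasons[rep$participant_id == "P02"], "low_logging")
  expect_false(rep$included[rep$participant_id == "P03"])
  expect_match(rep$reasons[rep$participant_id == "P03"], "short_tracking")
  expect_true(all(rep$included[rep$participant_id %in% c("P04", "P05")]))
  expect_true(all(res$daily$participant_id %in% c("P04", "P05")))
  # every excluded participant carries at least one reason code
  expect_true(all(nchar(rep$reasons[!rep$included]) > 0))
})

test_that("imputation is local, rule-respecting and idempotent", {
  cohort <- generate_cohort(cohort_config(n_participants = 3, n_days = 30,
                                          missing_rate = 0, seed = 31))
  d <- cohort$daily
  expect_identical(impute_missing(d), d) # nothing missing -> unchanged

  d2 <- d
  hole <- which(d2$participant_id == "P01")[10]
  d2$cho_g_per_kg[hole] <- NA
  filled <- impute_missing(d2)
  expect_false(anyNA(filled$cho_g_per_kg))
  # all other cells untouched
  expect_identical(filled[-hole, ], d[-hole, ])
  expect_identical(filled[hole, setdiff(names(d), "cho_g_per_kg")],
                   d[hole, setdiff(names(d), "cho_g_per_kg")])

  d3 <- d
  idx <- which(d3$participant_id == "P02")[c(3, 8)]
  d3$soreness[idx] <- NA
  filled3 <- impute_missing(d3)
  med <- median(d3$soreness[d3$participant_id == "P02"], na.rm = TRUE)
  expect_equal(filled3$soreness[idx], rep(as.integer(round(med)), 2))

  d4 <- d
  d4$soreness[d4$participant_id == "P03"] <- NA
  expect_error(impute_missing(d4), "P03", class = "wellcast_validation_error")
})

test_that("correlation pruning removes duplicates and nothing else", {
  set.seed(11)
  x <- tibble::tibble(a = rnorm(100), c = rnorm(100))
  x$b <- x$a
  pr <- prune_correlated(x, 0.85)
  expect_equal(ncol(pr$x), 2)
  expect_true("c" %in% names(pr$x))
  expect_equal(sum(c("a", "b") %in% names(pr$x)), 1)
  C <- abs(cor(as.matrix(pr$x))); diag(C) <- 0
  expect_true(max(C) <= 0.85)

  indep <- tibble::tibble(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  expect_equal(nrow(prune_correlated(indep)$removed), 0)

  const <- tibble::tibble(a = rnorm(50), z = rep(1, 50))
  prc <- prune_correlated(const)
  expect_equal(prc$removed$variable, "z")
  expect_equal(prc$removed$reason, "zero_variance")
})

test_that("pruning matches a brute-force re-implementation and is idempotent", {
  set.seed(17)
  for (i in 1:20) {
    n <- 120
    base <- matrix(rnorm(n * 3), n, 3)
    x <- tibble::tibble(
      x1 = base[, 1],
      x2 = base[, 1] * 0.95 + rnorm(n, 0, 0.25),
      x3 = base[, 1] * 0.5 + base[, 3] * 0.8,
      x4 = base[, 2],
      x5 = base[, 2] * 0.9 + rnorm(n, 0, 0.3))
    pr <- prune_correlated(x, 0.85)
    expect_equal(pr$removed$variable, naive_prune_order(x, 0.85))
    again <- prune_correlated(pr$x, 0.85)
    expect_equal(nrow(again$removed), 0)
    expect_identical(again$x, pr$x)
  }
})

test_that("Markov unfolding has the documented geometry", {
  dates <- as.Date("2024-03-04") + 0:9
  toy <- tibble::tibble(participant_id = "A", date = dates,
                        x1 = 1:10, x2 = (1:10) * 10, x3 = (1:10) * 100)
  uf <- markov_unfold(toy, 7, manifest = toy_manifest(c("x1", "x2", "x3")))
  expect_equal(nrow(uf), 3) # 10 - 7
  dyn_cols <- grep("^x[123](_lag[1-7])?$", names(uf), value = TRUE)
  expect_equal(length(dyn_cols), 24) # 3 x (7 + 1)
  expect_equal(uf$x1, 8:10)
  expect_equal(uf$x1_lag7, 1:3)
  expect_equal(uf$x2_lag3, c(50, 60, 70))

  id <- markov_unfold(toy, 0, manifest = toy_manifest(c("x1", "x2", "x3")))
  expect_equal(as.data.frame(id), as.data.frame(toy), ignore_attr = TRUE)
})

test_that("every lagged cell equals direct indexing within participant", {
  set.seed(23)
  dates <- as.Date("2024-01-01") + 0:19
  tab <- dplyr::bind_rows(
    tibble::tibble(participant_id = "A", date = dates,
                   u = rnorm(20), v = rnorm(20)),
    tibble::tibble(participant_id = "B", date = dates,
                   u = rnorm(20), v = rnorm(20)))
  uf <- markov_unfold(tab, 4, manifest = toy_manifest(c("u", "v")))
  for (p in c("A", "B")) {
    orig <- tab[tab$participant_id == p, ]
    part <- uf[uf$participant_id == p, ]
    for (k in 1:4) {
      for (col in c("u", "v")) {
        expect_equal(part[[paste0(col, "_lag", k)]],
                     orig[[col]][(5:20) - k], tolerance = 1e-12)
      }
    }
    # lag-0 columns reconstruct the original dynamic block exactly
    expect_equal(part$u, orig$u[5:20])
  }
  short <- dplyr::bind_rows(tab[tab$participant_id == "A", ][1:3, ],
                            tab[tab$participant_id == "B", ])
  expect_warning(uf_s <- markov_unfold(short, 4, manifest = toy_manifest(c("u", "v"))),
                 "too few rows")
  expect_false("A" %in% uf_s$participant_id)
})

test_that("variable-set selection respects manifest tags", {
  uf <- small_prep()$unfolded
  act <- select_variable_set(uf, "ACTIONABLE")
  banned <- c("am_prs_c", "sleep_index", "sleep_index_ma7", "sleep_quality",
              "ln_rmssd", "hrv_change", "hrv_ewma7", "resting_hr",
              "rhr_change", "rhr_ewma7")
  bases <- unique(sub("_lag[0-9]+$", "", names(act)))
  expect_false(any(banned %in% setdiff(bases, c("am_prs", "am_prs_c", "hrv_change"))))
  main <- select_variable_set(uf, "MAIN")
  expect_true(all(setdiff(names(act), names(main)) %in%
                    c("am_prs_c", "hrv_change"))) # ACTIONABLE subset of MAIN
  t5 <- c("soreness", "life_stress", "sleep_quality", "am_prs_c_lag1",
          "am_prs_c_lag2")
  sel <- select_variable_set(uf, "TOP5", features = t5)
  expect_true(all(t5 %in% names(sel)))
  expect_error(select_variable_set(uf, "WEIRD"), class = "wellcast_config_error")
  expect_error(select_variable_set(uf, "TOP5", features = "nope"),
               class = "wellcast_validation_error")
})

test_that("model data blocks same-day leakage by policy and outcome family", {
  uf <- small_prep()$unfolded
  md_prs <- build_model_data(uf, "am_prs", "MAIN")
  cols <- setdiff(names(md_prs), c("participant_id", "date", ".outcome"))
  lag0 <- cols[!grepl("_lag[0-9]+$", cols)]
  # the outcome's own same-day copy is gone, lagged copies remain
  expect_false("am_prs_c" %in% lag0)
  expect_true("am_prs_c_lag1" %in% cols)
  # post-morning variables only enter lagged under morning_only
  expect_false(any(c("tl", "cho_g_per_kg", "duration_min") %in% lag0))
  expect_true("tl_lag1" %in% cols)
  # morning measurements are allowed at lag 0
  expect_true(all(c("soreness", "sleep_quality", "ln_rmssd") %in% lag0))

  md_hrv <- build_model_data(uf, "hrv_change", "MAIN")
  cols_h <- setdiff(names(md_hrv), c("participant_id", "date", ".outcome"))
  lag0_h <- cols_h[!grepl("_lag[0-9]+$", cols_h)]
  expect_false(any(c("ln_rmssd", "hrv_change", "hrv_ewma7", "resting_hr",
                     "rhr_change", "rhr_ewma7") %in% lag0_h))
  expect_true(all(c("ln_rmssd_lag1", "hrv_change_lag1") %in% cols_h))

  md_all <- build_model_data(uf, "am_prs", "MAIN", same_day = "all")
  lag0_all <- setdiff(names(md_all), c("participant_id", "date", ".outcome"))
  expect_true("tl" %in% lag0_all)
})

test_that("unfolding attenuates residual autocorrelation of a linear fit", {
  uf <- small_prep()$unfolded
  md <- build_model_data(uf, "hrv_change", "MAIN")
  one <- md[md$participant_id == md$participant_id[1], ]
  r_plain <- one$.outcome - mean(one$.outcome)
  fit <- lm(.outcome ~ ln_rmssd_lag1 + hrv_ewma7_lag1 + hrv_change_lag1,
            data = one)
  a0 <- acf(r_plain, plot = FALSE)$acf[2]
  a1 <- acf(resid(fit), plot = FALSE)$acf[2]
  expect_lt(abs(a1), abs(a0))
})
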