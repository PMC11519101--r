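# Fixtures built once per test session and cached; everything is generated
# in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full cohort -> imputed feature table -> unfolded dataset
prep_cohort <- function(config) {
  cohort <- generate_cohort(config)
  inc <- apply_inclusion_rules(cohort$sessions, cohort$daily)
  daily_imp <- impute_missing(inc$daily)
  ft <- impute_missing(build_feature_table(inc$sessions, daily_imp))
  unfolded <- markov_unfold(ft, 7)
  list(cohort = cohort, inclusion = inc, features = ft, unfolded = unfolded)
}

small_prep <- function() fixture("small_prep", function() {
  prep_cohort(cohort_config(n_participants = 8, n_days = 42, seed = 42))
})

default_cohort <- function() fixture("default_cohort", function() {
  generate_cohort(cohort_config(seed = 99))
})

small_md <- function(outcome = "am_prs") {
  fixture(paste0("small_md_", outcome), function() {
    prune_model_data(build_model_data(small_prep()$unfolded, outcome, "MAIN"))
  })
}

# hand-built modelling table for closed-form checks
make_md <- function(df, outcome = "am_prs") {
  preds <- setdiff(names(df), c("participant_id", "date", ".outcome"))
  manifest <- tibble::tibble(
    variable = preds, category = "x", family = "x", dynamic = TRUE,
    morning = TRUE, main = TRUE, interaction = FALSE, actionable = TRUE)
  structure(df, class = c("wc_model_data", class(tibble::tibble())),
            outcome = outcome, variable_set = "MAIN", manifest = manifest)
}

# minimal manifest for unfolding toy tables
toy_manifest <- function(vars, dynamic = TRUE) {
  tibble::tibble(variable = vars, category = "x", family = "x",
                 dynamic = dynamic, morning = TRUE, main = TRUE,
                 interaction = FALSE, actionable = TRUE)
}

replicate_seed <- function(r) 1000L + 17L * r
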