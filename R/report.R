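fit_glance_row <- function(f) {
  tibble(
    outcome = f$outcome, level = f$level, variable_set = f$variable_set,
    learner = f$learner, participant_id = f$participant_id,
    rmse = f$rmse, rmse_lo = f$rmse_ci[1], rmse_hi = f$rmse_ci[2],
    rmse_sd = f$rmse_sd %||% NA_real_,
    r_squared = f$r_squared, r2_sd = f$r2_sd %||% NA_real_
  )
}

#' Summarise a list of fits as one table
#'
#' @param fits List of `wc_fit` objects.
#' @return Tibble with one row per fit, sorted by outcome then ascending
#'   RMSE.
#' @export
summarise_fits <- function(fits) {
  bind_rows(lapply(fits, fit_glance_row)) |>
    arrange(.data$outcome, .data$rmse)
}

#' Write the report bundle of a full analysis
#'
#' Emits the tabular products of a run: per-outcome group model-comparison
#' tables sorted ascending by RMSE, the individual-model summary, the
#' mixed-model comparison of model families with its compact letter
#' display, a per-participant RMSE long table for plotting, importance and
#' partial-dependence tables, and a markdown summary. Every table
#' round-trips through CSV.
#'
#' @param fits List of `wc_fit` objects; must contain an intercept-only
#'   baseline for every outcome present (comparisons are meaningless
#'   without one).
#' @param comparison Optional `wc_comparison` (or named list of them, keyed
#'   by outcome).
#' @param importance Optional named list of `wc_importance` objects.
#' @param pd Optional named list of `wc_pd` objects.
#' @param dir Output directory (created).
#' @return Invisibly, a character vector of the files written.
#' @export
render_report <- function(fits, comparison = NULL, importance = list(),
                          pd = list(), dir) {
  tab <- summarise_fits(fits)
  for (oc in unique(tab$outcome)) {
    has_baseline <- any(tab$learner == "intercept" & tab$outcome == oc)
    if (!has_baseline)
      stop_validation(paste("no intercept-only baseline fit for outcome", oc))
  }
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "figures"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(x, rel) {
    p <- file.path(dir, rel)
    utils::write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  wr(tab |> filter(.data$level == "group"), "tables/group_models.csv")
  ind <- tab |> filter(.data$level == "individual")
  if (nrow(ind)) {
    wr(ind |>
         group_by(.data$outcome, .data$variable_set, .data$learner) |>
         summarise(mean_rmse = mean(.data$rmse), sd_rmse = sd(.data$rmse),
                   mean_r2 = mean(.data$r_squared), n = dplyr::n(),
                   .groups = "drop") |>
         arrange(.data$outcome, .data$mean_rmse),
       "tables/individual_models.csv")
    wr(ind |> select("outcome", "variable_set", "learner",
                     "participant_id", "rmse", "r_squared"),
       "figures/rmse_by_participant.csv")
  }
  if (!is.null(comparison)) {
    cmp_list <- if (inherits(comparison, "wc_comparison")) list(all = comparison)
                else comparison
    cmp_tab <- bind_rows(lapply(names(cmp_list), function(nm) {
      cmp_list[[nm]]$means |> mutate(outcome = nm, .before = 1)
    }))
    wr(cmp_tab, "tables/comparison.csv")
    ctr_tab <- bind_rows(lapply(names(cmp_list), function(nm) {
      cmp_list[[nm]]$contrasts |> mutate(outcome = nm, .before = 1)
    }))
    wr(ctr_tab, "tables/comparison_contrasts.csv")
  }
  for (nm in names(importance)) {
    wr(importance[[nm]]$table, sprintf("figures/importance_%s.csv", nm))
  }
  for (nm in names(pd)) {
    p <- pd[[nm]]
    wr(tibble(feature = p$feature, grid = p$grid, profile = p$profile),
       sprintf("figures/pd_%s.csv", nm))
  }

  md <- c("# Daily recovery modelling report", "",
          sprintf("Generated: %d fits, %d outcomes.", nrow(tab),
                  length(unique(tab$outcome))), "",
          "## Group models (ascending RMSE)", "",
          paste(utils::capture.output(print(as.data.frame(
            tab |> filter(.data$level == "group") |>
              select("outcome", "variable_set", "learner", "rmse", "r_squared")
          ), digits = 3)), collapse = "\n"))
  writeLines(md, file.path(dir, "report.md"))
  paths <- c(paths, file.path(dir, "report.md"))
  invisible(paths)
}
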