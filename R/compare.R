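#' Sidak multiple-comparison adjustment
#'
#' Adjusts a p-value for `m` comparisons under independence:
#' `p_adj = 1 - (1 - p)^m`, capped at 1. Monotone in both `p` and `m`.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' sidak_adjust(0.01, 10) # 1 - 0.99^10 = 0.0956
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_domain("p must lie in [0, 1]")
  if (any(m < 1)) stop_domain("m must be >= 1")
  pmin(1 - (1 - p)^m, 1)
}

# compact letter display by greedy insert-and-absorb over the
# non-significance graph: types sharing a letter are not significantly
# different at alpha
compact_letters <- function(types, pairs, alpha = 0.05) {
  k <- length(types)
  nonsig <- matrix(TRUE, k, k, dimnames = list(types, types))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$type1[r]; b <- pairs$type2[r]
    ns <- pairs$p_adj[r] > alpha
    nonsig[a, b] <- ns
    nonsig[b, a] <- ns
  }
  # cover every non-significant pair with a clique grown greedily around it
  groups <- list()
  covered <- function(a, b) any(vapply(groups, function(g) all(c(a, b) %in% g),
                                       logical(1)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- types[i]; b <- types[j]
      if (!nonsig[a, b] || covered(a, b)) next
      g <- c(a, b)
      for (u in setdiff(types, g)) if (all(nonsig[u, g])) g <- c(g, u)
      groups <- c(groups, list(g))
    }
  }
  # isolated types (significantly different from everything) get their own letter
  for (t in types) {
    if (!any(vapply(groups, function(g) t %in% g, logical(1))))
      groups <- c(groups, list(t))
  }
  # absorb redundant subsets
  keep <- rep(TRUE, length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i != j && keep[j] && all(groups[[i]] %in% groups[[j]]) &&
          length(groups[[i]]) < length(groups[[j]])) keep[i] <- FALSE
    }
  }
  groups <- groups[keep]
  letters_out <- setNames(rep("", k), types)
  for (gi in seq_along(groups)) {
    for (t in groups[[gi]]) {
      letters_out[t] <- paste0(letters_out[t], letters[gi])
    }
  }
  letters_out
}

#' Compare model families across athletes with a linear mixed model
#'
#' Takes a long table of per-athlete RMSE values (one value per athlete per
#' model type) and fits a random-intercept linear mixed model with model
#' type as the fixed effect and athlete as the random effect. Estimated
#' marginal means per model type are computed with the emmeans package; all
#' pairwise contrasts are adjusted by the Sidak (default) or Tukey method,
#' and a compact letter display is derived from the significance graph —
#' model types sharing no letter differ significantly at `alpha`.
#'
#' @param rmse_table Tibble with columns `participant_id`, `model_type`,
#'   `rmse`; >= 2 model types and >= 3 athletes. Missing cells are allowed
#'   (the fit proceeds) and are reported.
#' @param adjust `"sidak"` (default) or `"tukey"`.
#' @param alpha Significance level for the letters (default 0.05).
#' @return A `wc_comparison`: `$means` (estimated marginal mean RMSE, SE
#'   and letters per model type, ascending by mean), `$contrasts` (pairwise
#'   estimates with adjusted p-values), `$adjust`, `$missing_cells`.
#' @export
compare_model_types <- function(rmse_table, adjust = c("sidak", "tukey"),
                                alpha = 0.05) {
  adjust <- match.arg(adjust)
  need <- c("participant_id", "model_type", "rmse")
  missing_cols <- setdiff(need, names(rmse_table))
  if (length(missing_cols))
    stop_validation(paste("rmse_table lacks:", paste(missing_cols, collapse = ", ")))
  rmse_table <- rmse_table |> filter(!is.na(.data$rmse))
  types <- unique(rmse_table$model_type)
  if (length(types) < 2) stop_validation("need >= 2 model types")
  if (length(unique(rmse_table$participant_id)) < 3)
    stop_validation("need >= 3 participants")

  full_grid <- tidyr::expand_grid(
    participant_id = unique(rmse_table$participant_id), model_type = types)
  missing_cells <- anti_join(full_grid, rmse_table,
                             by = c("participant_id", "model_type"))

  dat <- rmse_table |> mutate(model_type = factor(.data$model_type, levels = types))
  fit <- suppressMessages(lme4::lmer(rmse ~ model_type + (1 | participant_id),
                                     data = dat, REML = TRUE))
  emm <- emmeans::emmeans(fit, "model_type")
  means <- as.data.frame(emm) |>
    as_tibble() |>
    select(model_type = "model_type", mean_rmse = "emmean", se = "SE")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = adjust)) |>
    as_tibble()
  split_types <- strsplit(as.character(prs$contrast), " - ")
  contrasts <- tibble(
    type1 = trimws(vapply(split_types, `[[`, character(1), 1)),
    type2 = trimws(vapply(split_types, `[[`, character(1), 2)),
    estimate = prs$estimate, se = prs$SE, p_adj = prs$p.value
  )
  lt <- compact_letters(as.character(means$model_type), contrasts, alpha)
  means$letters <- lt[as.character(means$model_type)]
  means <- means |> arrange(.data$mean_rmse)

  structure(list(means = means, contrasts = contrasts, adjust = adjust,
                 alpha = alpha, missing_cells = missing_cells, lmm = fit),
            class = "wc_comparison")
}

#' @export
print.wc_comparison <- function(x, ...) {
  cat(sprintf("<wc_comparison> %s-adjusted pairwise contrasts (alpha = %g)\n",
              x$adjust, x$alpha))
  print(x$means)
  invisible(x)
}
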