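#' Plot an importance report
#'
#' Horizontal bar (aggregated / model-based) or boxplot-style (permutation,
#' using the retained repeat distribution) display of the top features.
#'
#' @param x A `wc_importance`.
#' @param top_n Features shown (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wc_importance <- function(x, top_n = 10, ...) {
  tab <- head(x$table, top_n)
  tab$feature <- factor(tab$feature, levels = rev(tab$feature))
  if (x$method == "permutation" && !is.null(x$repeats)) {
    long <- as_tibble(x$repeats[as.character(tab$feature), , drop = FALSE],
                      rownames = "feature") |>
      tidyr::pivot_longer(-"feature", values_to = "importance") |>
      mutate(feature = factor(.data$feature, levels = levels(tab$feature)))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$importance, y = .data$feature)) +
      ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
      ggplot2::labs(x = "RMSE increase after permutation", y = NULL,
                    title = sprintf("Permutation importance (%s, %s)",
                                    x$outcome, x$level)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$importance, y = .data$feature)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "Scaled importance", y = NULL,
                    title = sprintf("Variable importance (%s, %s)",
                                    x$outcome, x$level)) +
      ggplot2::theme_minimal()
  }
}

#' Plot a partial-dependence profile
#'
#' Mean predicted response over the feature grid; individual-observation
#' (ICE) curves are drawn in gray when retained.
#'
#' @param x A `wc_pd`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wc_pd <- function(x, ...) {
  df <- tibble(grid = x$grid, profile = x$profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$profile))
  if (!is.null(x$ice)) {
    ice_long <- as_tibble(x$ice) |>
      mutate(.row = dplyr::row_number()) |>
      tidyr::pivot_longer(-".row", names_to = ".g", values_to = "pred") |>
      mutate(grid = x$grid[as.integer(sub("^V", "", .data$.g))])
    p <- p + ggplot2::geom_line(
      data = ice_long,
      ggplot2::aes(x = .data$grid, y = .data$pred, group = .data$.row),
      color = "gray80", linewidth = 0.2)
  }
  p + ggplot2::geom_line(color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = x$feature, y = "Mean prediction",
                  title = sprintf("Partial dependence: %s (%s)", x$feature,
                                  x$outcome)) +
    ggplot2::theme_minimal()
}

#' Per-participant RMSE spread across model families
#'
#' Reproduces the classic "group vs individual model accuracy" panel: one
#' point per athlete per model type, ordered by the family's mean RMSE.
#'
#' @param fits List of `wc_fit` objects (individual level).
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(fits) {
  tab <- summarise_fits(fits) |> filter(.data$level == "individual")
  if (!nrow(tab)) stop_validation("no individual fits to plot")
  ord <- tab |> group_by(.data$variable_set) |>
    summarise(m = mean(.data$rmse), .groups = "drop") |> arrange(.data$m)
  tab$variable_set <- factor(tab$variable_set, levels = ord$variable_set)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$variable_set, y = .data$rmse)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "gray90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, color = "steelblue") +
    ggplot2::facet_wrap(~ .data$outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "RMSE") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
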