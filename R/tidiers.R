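#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold (or per-resample) metrics of a fit
#'
#' @param x A `wc_fit`.
#' @param ... Unused.
#' @return The fold-level (group fits) or bootstrap-resample-level
#'   (individual fits) metric tibble.
#' @export
tidy.wc_fit <- function(x, ...) x$metrics

#' One-row summary of a fit
#'
#' @param x A `wc_fit`.
#' @param ... Unused.
#' @return One-row tibble: identity columns plus RMSE (with 95% CI bounds
#'   and, for bootstrap-scored fits, SD) and R-squared.
#' @export
glance.wc_fit <- function(x, ...) fit_glance_row(x)

#' Tidy an importance report
#'
#' @param x A `wc_importance`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance`, ranked descending (plus spread
#'   columns where available).
#' @export
tidy.wc_importance <- function(x, ...) x$table

#' Tidy a partial-dependence profile
#'
#' @param x A `wc_pd`.
#' @param ... Unused.
#' @return Tibble `feature`, `grid`, `profile`.
#' @export
tidy.wc_pd <- function(x, ...) {
  tibble(feature = x$feature, grid = x$grid, profile = x$profile)
}

#' Tidy the pairwise contrasts of a model-family comparison
#'
#' @param x A `wc_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise contrasts with adjusted p-values.
#' @export
tidy.wc_comparison <- function(x, ...) x$contrasts

#' Estimated marginal means of a model-family comparison
#'
#' @param x A `wc_comparison`.
#' @param ... Unused.
#' @return Tibble of per-model-type estimated mean RMSE, SE and compact
#'   letters, ascending by mean.
#' @export
glance.wc_comparison <- function(x, ...) x$means
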