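# Scenario comparison statistics: summary tables of per-cell exceedance
# probabilities (mean, quartiles, median) for baseline vs irrigation, a
# one-sided Wilcoxon rank-sum test of whether irrigation increased the
# exceedance probabilities, and one-sided Welch t-tests on monthly coverage.

#' Summarise exceedance maps for a region, baseline vs irrigation
#'
#' Computes mean, 25th percentile, median, and 75th percentile of per-cell
#' exceedance probabilities over the unmasked region cells for each scenario
#' (quantiles by linear interpolation between order statistics), plus the
#' one-sided rank-sum p-value for the null that irrigation did not increase
#' the probabilities.
#'
#' @param baseline,irrigation `exceedance_map`s sharing grid, `T`, `period`.
#' @param region_cells Logical matrix or integer indices selecting the region.
#' @param region_label Label stored in the output rows.
#' @return A `data.frame` with one row per scenario and columns `region`,
#'   `T`, `period`, `scenario`, `mean`, `p25`, `median`, `p75`, `n_cells`,
#'   `wilcoxon_p` (identical in both rows).
#' @export
summarize_exceedance <- function(baseline, irrigation, region_cells,
                                 region_label = "REGION") {
  if (!identical(dim(baseline$values), dim(irrigation$values)) ||
      baseline$T != irrigation$T || baseline$period != irrigation$period) {
    stop("baseline and irrigation maps must share grid, T, and period")
  }
  cells <- if (is.logical(region_cells)) which(region_cells) else
    as.integer(region_cells)
  vals_b <- baseline$values[cells]
  vals_i <- irrigation$values[cells]
  keep <- !is.na(vals_b) & !is.na(vals_i)
  vals_b <- vals_b[keep]; vals_i <- vals_i[keep]
  if (length(vals_b) == 0L) stop("region is empty after masking")

  row_stats <- function(v, scen) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(region = region_label, T = baseline$T,
               period = baseline$period, scenario = scen,
               mean = mean(v), p25 = q[1], median = q[2], p75 = q[3],
               n_cells = length(v))
  }
  out <- rbind(row_stats(vals_b, "BASELINE"), row_stats(vals_i, "IRRIGATION"))
  wt <- wilcoxon_increase_test(vals_b, vals_i)
  out$wilcoxon_p <- wt$p_value
  out
}

#' One-sided Wilcoxon rank-sum test for an irrigation increase
#'
#' Tests the null that irrigation did not increase the values against the
#' alternative that the irrigation sample is stochastically greater. Exact
#' enumeration is used for small untied samples (both sizes <= 20); larger or
#' tied samples use the normal approximation with tie correction.
#'
#' @param baseline_values,irrigation_values Numeric samples.
#' @param exact `NULL` for the size-based default, or `TRUE`/`FALSE` to
#'   force a method.
#' @return List with `p_value`, `statistic` (rank-sum W), `method`, and
#'   `degenerate` (`TRUE` when every value in both samples is identical, in
#'   which case `p_value = 0.5`).
#' @export
wilcoxon_increase_test <- function(baseline_values, irrigation_values,
                                   exact = NULL) {
  b <- baseline_values[!is.na(baseline_values)]
  i <- irrigation_values[!is.na(irrigation_values)]
  if (length(b) == 0L || length(i) == 0L) stop("both samples must be non-empty")
  if (length(unique(c(b, i))) == 1L) {
    return(list(p_value = 0.5, statistic = NA_real_, method = "degenerate",
                degenerate = TRUE))
  }
  ties <- anyDuplicated(c(b, i)) > 0L
  if (is.null(exact)) exact <- !ties && length(b) <= 20L && length(i) <= 20L
  if (exact && ties) {
    stop("exact enumeration requires untied samples")
  }
  wt <- suppressWarnings(
    wilcox.test(i, b, alternative = "greater", exact = exact,
                correct = !exact)
  )
  list(p_value = unname(wt$p.value), statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal approximation",
       degenerate = FALSE)
}

#' One-sided Welch t-test on a month's daily coverage
#'
#' Tests whether irrigation increased the mean daily fractional coverage for
#' a calendar month, using Welch's unequal-variance two-sample t-test.
#'
#' @param baseline_series,irrigation_series [coverage_series()] objects
#'   covering the month fully.
#' @param month Calendar month (1-12).
#' @return List with `t_stat`, `p_value`, `significant_at_0.01`, and
#'   `degenerate` (`TRUE` with `p_value = 0.5` when both samples have zero
#'   variance and equal means).
#' @export
monthly_coverage_test <- function(baseline_series, irrigation_series, month) {
  pick <- function(s) s$F[date_months(s$date) == month]
  b <- pick(baseline_series); i <- pick(irrigation_series)
  if (length(b) == 0L || length(i) == 0L) {
    stop("month ", month, " is not covered by both series")
  }
  if (sd(b) == 0 && sd(i) == 0) {
    if (mean(b) == mean(i)) {
      return(list(t_stat = 0, p_value = 0.5, significant_at_0.01 = FALSE,
                  degenerate = TRUE))
    }
    # constant but shifted samples: direction is unambiguous
    p <- if (mean(i) > mean(b)) 0 else 1
    return(list(t_stat = ifelse(p == 0, Inf, -Inf), p_value = p,
                significant_at_0.01 = p < 0.01, degenerate = TRUE))
  }
  tt <- t.test(i, b, alternative = "greater", var.equal = FALSE)
  list(t_stat = unname(tt$statistic), p_value = unname(tt$p.value),
       significant_at_0.01 = tt$p.value < 0.01, degenerate = FALSE)
}
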