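# Habitat metrics derived from the Wetness Index: exceedance-probability
# maps (fraction of a period's days on which a cell's ponding run exceeds T),
# stream masking by flowrate persistence, daily fractional coverage of a
# region, monthly coverage means with confidence intervals, and habitat
# stability classification from maximum ponding duration.

#' Mask persistently fast-flowing cells
#'
#' Anopheles larvae rarely survive in fast-moving water, so cells whose
#' simulated flowrate exceeds `q_threshold` for at least `persistence` of the
#' year's days are masked out of habitat statistics.
#'
#' @param flow A `flow_cube` covering the full year.
#' @param q_threshold Flowrate threshold (m^3/s).
#' @param persistence Minimum fraction of days above threshold.
#' @return Logical matrix, `TRUE` where masked.
#' @export
stream_mask <- function(flow, q_threshold = 0.01, persistence = 0.9) {
  frac <- apply(flow$values > q_threshold, c(1, 2), mean)
  frac >= persistence
}

#' Exceedance-probability map P(WI > T)
#'
#' Per unmasked cell, the fraction of the period's days on which the Wetness
#' Index strictly exceeds `T`. The dry period pools its two non-contiguous
#' month blocks into one day set. WI values come from the year-long
#' recurrence; the period only windows them.
#'
#' @param wi A `wetness_cube`.
#' @param T Duration threshold in days (>= 1); 10 and 15 days correspond to
#'   larval development under critical and normal conditions.
#' @param period `"YEAR"`, `"DRY"`, or `"RAINY"`.
#' @param seasons A [season_definition()].
#' @param mask Optional logical matrix; masked cells are `NA`, not zero.
#' @return An `exceedance_map`: `values` matrix in \[0, 1\] (NA where
#'   masked), plus `T`, `period`, `scenario_label`, `mask_applied`.
#' @export
exceedance_probability <- function(wi, T, period = "YEAR",
                                   seasons = season_definition(),
                                   mask = NULL) {
  if (T < 1) stop("T must be at least 1 day")
  idx <- period_index(wi$dates, period, seasons)
  if (length(idx) == 0L) stop("period contains no days of the cube calendar")
  p <- apply(wi$values[, , idx, drop = FALSE] > T, c(1, 2), mean)
  if (!is.null(mask)) p[mask] <- NA_real_
  structure(
    list(values = p, T = T, period = toupper(period),
         scenario_label = wi$scenario_label, mask_applied = !is.null(mask)),
    class = "exceedance_map"
  )
}

#' Daily fractional habitat coverage F(WI > T) of a region
#'
#' Per day, the fraction of the region's cells whose Wetness Index exceeds
#' `T`. The strict comparator is the default; `comparator = "geq"` switches
#' to `WI >= T`.
#'
#' @param wi A `wetness_cube`.
#' @param T Duration threshold in days.
#' @param region_cells Logical matrix or integer cell indices selecting the
#'   region (e.g. `farm_id > 0`).
#' @param comparator `"gt"` (strict, default) or `"geq"`.
#' @return A `coverage_series` data.frame with columns `date` and `F`;
#'   attributes `T`, `region_size`, `comparator`.
#' @export
coverage_series <- function(wi, T, region_cells, comparator = c("gt", "geq")) {
  comparator <- match.arg(comparator)
  cells <- if (is.logical(region_cells)) which(region_cells) else
    as.integer(region_cells)
  if (length(cells) == 0L) stop("region_cells must select at least one cell")
  d <- dim(wi$values)
  flat <- matrix(wi$values, d[1] * d[2], d[3])[cells, , drop = FALSE]
  f <- if (comparator == "gt") colMeans(flat > T) else colMeans(flat >= T)
  structure(
    data.frame(date = wi$dates, F = f),
    T = T, region_size = length(cells), comparator = comparator,
    scenario_label = wi$scenario_label,
    class = c("coverage_series", "data.frame")
  )
}

#' Monthly mean fractional coverage with 95% confidence intervals
#'
#' Per calendar month, the mean of the daily coverage values and a normal-
#' approximation 95% CI (`mean +/- 1.96 * sd / sqrt(n_days)`). Months not
#' fully covered by the series are flagged `partial`, not silently included.
#'
#' @param series A [coverage_series()].
#' @return data.frame with `month`, `mean`, `ci_low`, `ci_high`, `n_days`,
#'   `partial`.
#' @export
monthly_mean_coverage <- function(series) {
  months <- date_months(series$date)
  years <- as.integer(format(series$date, "%Y"))
  out <- do.call(rbind, lapply(sort(unique(months)), function(m) {
    sel <- months == m
    f <- series$F[sel]
    n <- length(f)
    mu <- mean(f)
    half <- 1.96 * sd(f) / sqrt(n)
    full_len <- sum(vapply(unique(years[sel]), function(y) {
      first <- as.Date(sprintf("%d-%02d-01", y, m))
      as.integer(seq(first, by = "month", length.out = 2)[2] - first)
    }, integer(1)))
    data.frame(month = m, mean = mu, ci_low = mu - half, ci_high = mu + half,
               n_days = n, partial = n < full_len)
  }))
  rownames(out) <- NULL
  out
}

STABILITY_LEVELS <- c("NON_HABITAT", "TEMPORARY", "SEMI_PERMANENT", "PERMANENT")

#' Classify habitat stability from maximum ponding duration
#'
#' Cells are classed by the longest ponding run they achieve in the year:
#' non-habitat (< 15 days), temporary (15-90 days), semi-permanent (90-180
#' days), permanent (>= 180 days); boundaries are left-closed. A histogram of
#' maximum durations over 15-day bins is included, with a final open bin for
#' 360 days and above.
#'
#' @param max_duration Integer matrix of per-cell maximum ponding durations
#'   (see [max_ponding_duration()]).
#' @param mask Optional logical matrix; masked cells are excluded from
#'   classes, fractions, and the histogram.
#' @return A `stability_map`: `class` (character matrix, `NA` where masked),
#'   `max_duration`, `fractions` (named, sums to 1 over unmasked cells),
#'   `histogram` data.frame (`bin_start`, `bin_end`, `count`, `fraction`).
#' @export
classify_stability <- function(max_duration, mask = NULL) {
  if (any(max_duration < 0, na.rm = TRUE)) {
    stop("max_duration must be non-negative")
  }
  cls <- matrix(STABILITY_LEVELS[
    findInterval(max_duration, c(0, 15, 90, 180))],
    nrow(max_duration), ncol(max_duration))
  if (!is.null(mask)) cls[mask] <- NA_character_
  use <- if (is.null(mask)) rep(TRUE, length(max_duration)) else !mask
  dur <- max_duration[use]

  fractions <- vapply(STABILITY_LEVELS,
                      function(l) mean(cls[use] == l), numeric(1))

  breaks <- seq(0, 360, by = 15)
  bin <- findInterval(dur, breaks)        # 25 = open top bin [360, Inf)
  counts <- tabulate(bin, nbins = length(breaks))
  histogram <- data.frame(
    bin_start = breaks,
    bin_end = c(breaks[-1], Inf),
    count = counts,
    fraction = counts / max(length(dur), 1L)
  )
  structure(
    list(class = cls, max_duration = max_duration, fractions = fractions,
         histogram = histogram),
    class = "stability_map"
  )
}

#' @export
print.stability_map <- function(x, ...) {
  cat("<stability_map> class fractions over unmasked cells:\n")
  print(round(x$fractions, 4))
  invisible(x)
}
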