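# Wetness Index: per-cell count of consecutive ponded days. A cell is ponded
# on a day when its surface-layer saturation meets the threshold theta; the
# index increments by one on each ponded day and resets to zero otherwise,
# starting from zero before the first simulated day.

#' Compute the Wetness Index cube
#'
#' For each cell, `WI(t) = WI(t-1) + 1` if `S(t) >= theta`, else 0, with
#' `WI = 0` before day one. The index is computed over the full simulated
#' year; seasonal analyses window the resulting cube rather than restarting
#' the recurrence at season boundaries.
#'
#' @param sat A `sat_cube`.
#' @param theta Ponding saturation threshold in \[0, 1\].
#' @return A `wetness_cube`: integer array of ponding-run lengths with the
#'   input calendar and `theta` attached.
#' @examples
#' sat <- structure(list(values = array(c(0.5, 0.49, 0.4, 0.48),
#'                                      dim = c(1, 1, 4)),
#'                       dates = make_dates(2018)[1:4],
#'                       scenario_label = "demo"),
#'                  class = c("sat_cube", "pondwi_cube"))
#' compute_wi(sat, 0.48)$values[1, 1, ]  # 1 2 0 1
#' @export
compute_wi <- function(sat, theta) {
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  v <- sat$values
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN saturation at cell (%d, %d) on %s",
                 idx[1], idx[2], sat$dates[idx[3]]))
  }
  d <- dim(v)
  wi <- array(0L, dim = d)
  prev <- matrix(0L, d[1], d[2])
  for (t in seq_len(d[3])) {
    prev <- (prev + 1L) * (v[, , t] >= theta)
    wi[, , t] <- prev
  }
  out <- new_cube(wi, sat$dates, sat$scenario_label, "wetness_index",
                  "wetness_cube")
  out$theta <- theta
  out
}

#' Maximum ponding duration per cell
#'
#' The longest ponding run each cell achieves within a window, i.e. the
#' maximum Wetness Index over the window's days.
#'
#' @param wi A `wetness_cube`.
#' @param window `NULL` for the full calendar, or a length-2 `Date` range.
#' @return Integer matrix of maximum durations (days).
#' @export
max_ponding_duration <- function(wi, window = NULL) {
  idx <- window_index(wi$dates, window)
  apply(wi$values[, , idx, drop = FALSE], c(1, 2), max)
}
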