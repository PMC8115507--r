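# Rotating sprinkler irrigation over four farm parcels: two groups alternate
# 10-day turns through the dry season, each on-turn farm receiving 10 mm/day
# (delivered over 22 h; at daily resolution the spread is metadata only).

#' Define a rotating irrigation schedule
#'
#' Farms are split into two groups that alternate fixed-length turns, group A
#' first, counting calendar days from the first day of the year that falls in
#' an active month. Outside the active months nothing is irrigated.
#'
#' @param group_a,group_b Farm ids in each rotation group (disjoint).
#' @param turn_length Days per irrigation turn.
#' @param daily_depth Irrigation depth applied on-turn (mm/day).
#' @param hours_per_day Sub-daily application window (h); recorded as
#'   metadata, not resolved at the daily time step.
#' @param active_months Months in which irrigation runs (default: the dry
#'   season, January-April and November-December).
#' @param enabled If `FALSE` the schedule applies no water (baseline).
#' @return An object of class `irrigation_schedule`.
#' @export
irrigation_schedule <- function(group_a = c(1L, 3L), group_b = c(2L, 4L),
                                turn_length = 10L, daily_depth = 10,
                                hours_per_day = 22,
                                active_months = c(1:4, 11:12),
                                enabled = TRUE) {
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("group_a and group_b must be disjoint")
  }
  if (turn_length < 1L) stop("turn_length must be at least 1 day")
  if (daily_depth < 0) stop("daily_depth must be non-negative")
  stopifnot_flag(enabled, "enabled")
  structure(
    list(group_a = as.integer(group_a), group_b = as.integer(group_b),
         turn_length = as.integer(turn_length), daily_depth = daily_depth,
         hours_per_day = hours_per_day,
         active_months = as.integer(active_months), enabled = enabled),
    class = "irrigation_schedule"
  )
}

#' Irrigation depth applied to a farm on a given day
#'
#' @param schedule An [irrigation_schedule()].
#' @param farm_id Farm parcel id; 0 (outside farms) always receives 0.
#' @param date A `Date`.
#' @return Depth in mm/day (`daily_depth` when the farm's group is on-turn in
#'   an active month, else 0).
#' @examples
#' sch <- irrigation_schedule()
#' irrigation_depth(sch, 1, as.Date("2018-01-05"))  # 10
#' irrigation_depth(sch, 2, as.Date("2018-01-05"))  # 0
#' @export
irrigation_depth <- function(schedule, farm_id, date) {
  if (farm_id == 0L) return(0)
  if (!farm_id %in% c(schedule$group_a, schedule$group_b)) {
    stop("farm_id ", farm_id, " is not in either irrigation group")
  }
  if (!schedule$enabled) return(0)
  date <- as.Date(date)
  month <- as.integer(format(date, "%m"))
  if (!month %in% schedule$active_months) return(0)
  first_active <- first_active_day(schedule, as.integer(format(date, "%Y")))
  if (date < first_active) return(0)
  days_since <- as.integer(date - first_active)
  group_a_on <- (days_since %/% schedule$turn_length) %% 2L == 0L
  on_turn <- if (farm_id %in% schedule$group_a) group_a_on else !group_a_on
  if (on_turn) schedule$daily_depth else 0
}

# First calendar day of `year` whose month is active.
first_active_day <- function(schedule, year) {
  dates <- make_dates(year)
  dates[which(date_months(dates) %in% schedule$active_months)[1]]
}

# Daily irrigation depth per farm id (rows: farm 1..4) for a calendar;
# vectorised helper for the bucket model.
irrigation_matrix <- function(schedule, dates) {
  farms <- sort(unique(c(schedule$group_a, schedule$group_b)))
  out <- matrix(0, nrow = length(farms), ncol = length(dates),
                dimnames = list(farms, NULL))
  if (!schedule$enabled || schedule$daily_depth == 0) return(out)
  for (f in farms) {
    out[as.character(f), ] <- vapply(
      dates, function(d) irrigation_depth(schedule, f, d), numeric(1)
    )
  }
  out
}
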