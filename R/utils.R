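#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats median quantile rbinom rgamma rnorm runif sd t.test
#'   wilcox.test qnorm
#' @importFrom utils head modifyList
NULL

# Run code with a private RNG stream: seeds locally, restores any global
# .Random.seed afterwards so callers never see package randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stage seed from a root seed; keeps results < 2^31 and stages
# decorrelated without touching global RNG state.
derive_seed <- function(seed, stage) {
  offsets <- c(
    domain = 11L, forcing = 23L, bucket = 37L, survey = 53L,
    calibration = 71L, stats = 89L
  )
  off <- offsets[[stage]]
  (as.integer(seed) * 1103L + off * 12289L) %% 2147483587L
}

#' Build a daily calendar for one simulation year
#'
#' @param year Calendar year (integer). The study design simulates one full
#'   year at daily resolution.
#' @return A `Date` vector covering every day of `year`.
#' @export
make_dates <- function(year = 2018) {
  seq(as.Date(sprintf("%d-01-01", year)),
      as.Date(sprintf("%d-12-31", year)), by = "day")
}

date_months <- function(dates) as.integer(format(dates, "%m"))

#' Dry/rainy season month definitions
#'
#' The study calendar splits the year into a dry season (January-April plus
#' November-December) and a rainy season (May-October).
#'
#' @param dry_months Integer months of the dry season.
#' @param rainy_months Integer months of the rainy season.
#' @return An object of class `season_definition`.
#' @export
season_definition <- function(dry_months = c(1:4, 11:12), rainy_months = 5:10) {
  dry_months <- sort(unique(as.integer(dry_months)))
  rainy_months <- sort(unique(as.integer(rainy_months)))
  if (length(intersect(dry_months, rainy_months)) > 0L) {
    stop("dry and rainy months must be disjoint")
  }
  if (!setequal(c(dry_months, rainy_months), 1:12)) {
    stop("dry and rainy months together must cover all 12 months")
  }
  structure(
    list(dry_months = dry_months, rainy_months = rainy_months,
         year_months = 1:12),
    class = "season_definition"
  )
}

period_months <- function(period, seasons = season_definition()) {
  switch(toupper(period),
    YEAR  = seasons$year_months,
    DRY   = seasons$dry_months,
    RAINY = seasons$rainy_months,
    stop("unknown period: ", period)
  )
}

# Time indices of a cube calendar falling in a period.
period_index <- function(dates, period, seasons = season_definition()) {
  which(date_months(dates) %in% period_months(period, seasons))
}

# Resolve a date window (length-2 Date vector, or NULL for the full
# calendar) to time indices, validating containment.
window_index <- function(dates, window) {
  if (is.null(window)) return(seq_along(dates))
  window <- as.Date(window)
  idx <- which(dates >= min(window) & dates <= max(window))
  if (length(idx) == 0L) stop("window contains no days of the cube calendar")
  idx
}

stopifnot_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(nm, " must be TRUE or FALSE")
  }
}
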