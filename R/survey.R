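# Synthetic larval-habitat survey: ponded locations observed during the
# rainy season, each tagged with a habitat type. A share of points gets
# types the hydrologic model cannot represent (man-made ponds, tire tracks,
# animal footprints); threshold calibration filters those out.

SIMULATABLE_TYPES <- c("rain_pool", "stream_shoreline", "irrigation_canal",
                       "hippo_trench", "drainage_ditch", "rice_puddle")
EXCLUDED_TYPES <- c("man_made_pond", "tire_track", "animal_footprint")

#' Generate synthetic survey points at ponded locations
#'
#' Samples cells whose rainy-season maximum saturation reaches `theta_true`,
#' so the planted ponding threshold is recoverable by calibration: the sample
#' is guaranteed to contain at least one anchor point whose rainy-season
#' maximum saturation lies within one threshold-grid step above `theta_true`
#' (the strictest threshold that still detects every point is then
#' `theta_true` itself).
#'
#' @param sat A `sat_cube`.
#' @param domain The matching `domain_grid`.
#' @param theta_true Planted ponding threshold (saturation fraction).
#' @param n_points Number of survey rows.
#' @param seed Integer seed.
#' @param frac_excluded_types Share of points assigned habitat types the
#'   model cannot simulate (removed later by [filter_survey()]). With
#'   `frac_excluded_types = 1` even the anchor point is excluded, so
#'   calibration on the filtered table fails, as it should.
#' @param grid_step Threshold grid step the anchor guarantee refers to.
#' @param seasons A [season_definition()]; points are rainy-season
#'   observations.
#' @return A `data.frame` with columns `point_id`, `row`, `col` (1-based),
#'   `season`, `habitat_type`, `larvae_present`.
#' @export
make_survey <- function(sat, domain, theta_true = 0.48, n_points = 134,
                        seed = 1L, frac_excluded_types = 0.24,
                        grid_step = 0.01, seasons = season_definition()) {
  if (theta_true <= 0 || theta_true >= 1) stop("theta_true must be in (0, 1)")
  if (n_points < 1) stop("n_points must be at least 1")
  rainy_idx <- period_index(sat$dates, "RAINY", seasons)
  max_s <- apply(sat$values[, , rainy_idx, drop = FALSE], c(1, 2), max)

  eligible <- which(max_s >= theta_true)
  if (length(eligible) == 0L) {
    stop("unpondable domain: no cell reaches saturation ", theta_true,
         " in the rainy season")
  }
  anchor_pool <- eligible[max_s[eligible] < theta_true + grid_step]
  if (length(anchor_pool) == 0L) {
    stop("no cell pins the threshold: smallest rainy-season max saturation ",
         "above theta_true is ", signif(min(max_s[eligible]), 4),
         ", more than one grid step above ", theta_true)
  }

  with_seed(derive_seed(seed, "survey"), {
    anchor <- if (length(anchor_pool) == 1L) anchor_pool else
      sample(anchor_pool, 1L)
    rest_pool <- setdiff(eligible, anchor)
    n_rest <- min(n_points - 1L, length(rest_pool))
    rest <- if (n_rest > 0L) {
      if (length(rest_pool) == 1L) rest_pool else
        sample(rest_pool, n_rest, replace = length(rest_pool) < n_rest)
    } else integer(0)
    cells <- c(anchor, rest)
    n_out <- length(cells)

    n_excl <- round(frac_excluded_types * n_out)
    types <- sample(SIMULATABLE_TYPES, n_out, replace = TRUE)
    if (n_excl > 0L) {
      # Excluded types go to non-anchor rows first so the anchor survives
      # filtering; only frac = 1 sacrifices it.
      excl_rows <- if (n_excl >= n_out) seq_len(n_out) else 1L + seq_len(n_excl)
      types[excl_rows] <- sample(EXCLUDED_TYPES, length(excl_rows),
                                 replace = TRUE)
    }

    nr <- domain$n_rows
    data.frame(
      point_id = sprintf("pt%03d", seq_len(n_out)),
      row = ((cells - 1L) %% nr) + 1L,
      col = ((cells - 1L) %/% nr) + 1L,
      season = "RAINY",
      habitat_type = types,
      larvae_present = runif(n_out) < 0.7,
      stringsAsFactors = FALSE
    )
  })
}
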