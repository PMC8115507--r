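# Ponding-threshold calibration: choose the saturation threshold theta that
# maximises the probability of detection (POD) of surveyed ponding locations,
# taking the largest theta attaining the maximal POD (the strictest threshold
# that still detects the points, minimising overprediction, which the survey
# cannot measure). Bootstrap resampling gives the selection distribution;
# the reported theta* is the median of per-resample selections.

#' Filter a survey table for calibration
#'
#' Removes habitat types the hydrologic model cannot simulate (man-made
#' ponds, tire tracks, animal footprints) and restricts to rainy-season
#' observations, since dry-season ponding is dominated by the simplified
#' irrigation scheme.
#'
#' @param survey Survey `data.frame` (see [make_survey()]).
#' @return The filtered survey.
#' @export
filter_survey <- function(survey) {
  keep <- !(survey$habitat_type %in% EXCLUDED_TYPES) &
    survey$season == "RAINY"
  out <- survey[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no usable survey points after filtering")
  rownames(out) <- NULL
  out
}

# Per-point maximum saturation over a set of days.
point_max_sat <- function(sat, points, idx) {
  nr <- dim(sat$values)[1]; nc <- dim(sat$values)[2]
  bad <- points$row < 1 | points$row > nr | points$col < 1 | points$col > nc
  if (any(bad)) {
    stop("survey point outside grid: ", points$point_id[which(bad)[1]])
  }
  flat <- matrix(sat$values, nr * nc, dim(sat$values)[3])
  cells <- (points$col - 1L) * nr + points$row
  apply(flat[cells, idx, drop = FALSE], 1, max)
}

#' Probability of detection at a threshold
#'
#' A point is detected when its containing cell's saturation reaches `theta`
#' on at least one day of the season window; POD is the detected fraction.
#'
#' @param sat A `sat_cube`.
#' @param points Survey rows (already filtered).
#' @param theta Saturation threshold.
#' @param season_window `NULL` for the full calendar, or a length-2 `Date`
#'   range (typically the rainy season).
#' @return POD in \[0, 1\].
#' @export
pod <- function(sat, points, theta, season_window = NULL) {
  if (nrow(points) == 0L) stop("points must be non-empty")
  idx <- window_index(sat$dates, season_window)
  mean(point_max_sat(sat, points, idx) >= theta)
}

#' Calibrate the ponding threshold by POD maximisation with bootstrap
#'
#' For each bootstrap resample (points drawn with replacement as the
#' calibration set, out-of-bag points as the validation set), the largest
#' theta on the grid `{0, step, ..., 1}` attaining the maximal calibration
#' POD is selected. `theta_star` is the median of the per-resample
#' selections, rounded to the grid.
#'
#' @param sat A `sat_cube`.
#' @param survey Filtered survey table (see [filter_survey()]).
#' @param theta_grid_step Grid step in (0, 0.5].
#' @param n_bootstrap Number of resamples (>= 1).
#' @param seed Integer seed.
#' @param season_window Detection window; defaults to the rainy-season days
#'   of the cube calendar.
#' @param seasons A [season_definition()] used for the default window.
#' @return A `calibration_result`: `theta_star`, the full-survey `pod_curve`
#'   over the grid, per-resample `bootstrap_thetas`, `pod_calibration`
#'   (POD at `theta_star` on the full survey), `pod_validation` (mean
#'   out-of-bag POD at each resample's selection; empty out-of-bag sets are
#'   recorded as missing, not zero), `n_points_used`, and `settings`.
#' @export
calibrate_theta <- function(sat, survey, theta_grid_step = 0.01,
                            n_bootstrap = 1000L, seed = 1L,
                            season_window = NULL,
                            seasons = season_definition()) {
  if (theta_grid_step <= 0 || theta_grid_step > 0.5) {
    stop("theta_grid_step must be in (0, 0.5]")
  }
  if (n_bootstrap < 1L) stop("n_bootstrap must be at least 1")
  if (nrow(survey) == 0L) stop("no usable survey points")

  idx <- if (is.null(season_window)) {
    period_index(sat$dates, "RAINY", seasons)
  } else {
    window_index(sat$dates, season_window)
  }
  max_s <- point_max_sat(sat, survey, idx)
  grid <- seq(0, 1, by = theta_grid_step)
  n <- length(max_s)

  # detection[i, g]: point i detected at grid threshold g
  detection <- outer(max_s, grid, `>=`)
  pod_curve <- colMeans(detection)

  select_theta <- function(rows) {
    curve <- colMeans(detection[rows, , drop = FALSE])
    grid[max(which(curve == max(curve)))]
  }

  with_seed(derive_seed(seed, "calibration"), {
    boot_thetas <- numeric(n_bootstrap)
    boot_val_pod <- rep(NA_real_, n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      cal <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(cal))
      th <- select_theta(cal)
      boot_thetas[b] <- th
      if (length(oob) > 0L) {
        boot_val_pod[b] <- mean(max_s[oob] >= th)
      }
    }
    theta_star <- grid[which.min(abs(grid - median(boot_thetas)))]
    structure(
      list(
        theta_star = theta_star,
        pod_curve = data.frame(theta = grid, pod = pod_curve),
        bootstrap_thetas = boot_thetas,
        pod_calibration = mean(max_s >= theta_star),
        pod_validation = if (all(is.na(boot_val_pod))) NA_real_ else
          mean(boot_val_pod, na.rm = TRUE),
        n_points_used = n,
        settings = list(theta_grid_step = theta_grid_step,
                        n_bootstrap = n_bootstrap, seed = seed,
                        season = "RAINY")
      ),
      class = "calibration_result"
    )
  })
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> theta* = %.3f (n = %d points, %d resamples)\n",
              x$theta_star, x$n_points_used, x$settings$n_bootstrap))
  cat(sprintf("  POD at theta*: calibration %.3f, validation %.3f\n",
              x$pod_calibration, x$pod_validation))
  invisible(x)
}
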