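make_points <- function(rows, cols, types = "rain_pool", season = "RAINY") {
  data.frame(
    point_id = sprintf("pt%03d", seq_along(rows)),
    row = rows, col = cols, season = season,
    habitat_type = rep_len(types, length(rows)),
    larvae_present = TRUE, stringsAsFactors = FALSE
  )
}

test_that("survey filtering drops unsimulatable types and dry-season rows", {
  survey <- rbind(
    make_points(1:70, 1:70, "rain_pool"),
    make_points(1:32, 1:32, c("man_made_pond", "tire_track",
                              "animal_footprint")),
    make_points(1:32, 1:32, "stream_shoreline", season = "DRY")
  )
  kept <- filter_survey(survey)
  expect_equal(nrow(kept), 70)
  expect_true(all(kept$season == "RAINY"))

  clean <- make_points(1:5, 1:5, "rain_pool")
  expect_identical(filter_survey(clean), clean)
  expect_error(filter_survey(make_points(1:5, 1:5, "tire_track")),
               "no usable survey points")
})

test_that("POD behaves at the threshold extremes and matches brute force", {
  sat <- random_sat_cube(10, 10, 120, seed = 5)
  sat$values <- sat$values * 0.99   # keep everything strictly below 1
  pts <- make_points(c(2, 5, 9), c(3, 3, 8))
  expect_equal(pod(sat, pts, 0), 1)
  expect_equal(pod(sat, pts, 1), 0)

  theta <- 0.8
  brute <- mean(vapply(seq_len(nrow(pts)), function(i) {
    any(sat$values[pts$row[i], pts$col[i], ] >= theta)
  }, logical(1)))
  expect_equal(pod(sat, pts, theta), brute)
  expect_error(pod(sat, make_points(99, 1), 0.5), "pt001")
})

test_that("POD is non-increasing in the threshold", {
  sat <- random_sat_cube(12, 12, 80, seed = 8)
  pts <- make_points(sample(1:12, 20, TRUE), sample(1:12, 20, TRUE))
  grid <- seq(0, 1, 0.05)
  pods <- vapply(grid, function(th) pod(sat, pts, th), numeric(1))
  expect_true(all(diff(pods) <= 0))
})

test_that("a single point pins theta* at its maximum saturation", {
  s <- array(0.2, dim = c(3, 3, 200))
  s[2, 2, 150] <- 0.60
  sat <- toy_cube(s)
  pts <- make_points(2, 2)
  res <- calibrate_theta(sat, pts, theta_grid_step = 0.01, n_bootstrap = 1,
                         seed = 1, season_window = range(sat$dates))
  expect_equal(res$theta_star, 0.60)
  expect_equal(res$pod_calibration, 1)
})

test_that("every bootstrap selection is the largest theta at maximal POD", {
  sim <- default_sim()
  survey <- filter_survey(make_survey(sim$baseline$saturation, sim$domain,
                                      theta_true = 0.48, n_points = 60,
                                      seed = 4))
  grid <- seq(0, 1, 0.01)
  set.seed(31)
  for (rep in 1:10) {
    rows <- sample.int(nrow(survey), nrow(survey), replace = TRUE)
    resample <- survey[rows, ]
    pods <- vapply(grid, function(th) {
      pod(sim$baseline$saturation, resample, th,
          season_window = as.Date(c("2018-05-01", "2018-10-31")))
    }, numeric(1))
    sel <- grid[max(which(pods == max(pods)))]
    above <- pods[grid > sel]
    if (length(above) > 0) expect_true(all(above < max(pods)))
  }
  # the reported theta* is the grid-rounded median of bootstrap selections
  res <- calibrate_theta(sim$baseline$saturation, survey,
                         theta_grid_step = 0.01, n_bootstrap = 50, seed = 4)
  expect_lte(abs(res$theta_star - median(res$bootstrap_thetas)), 0.005 + 1e-9)
})

test_that("calibration recovers a planted threshold", {
  sim <- default_sim()
  survey <- filter_survey(make_survey(sim$baseline$saturation, sim$domain,
                                      theta_true = 0.48, n_points = 102,
                                      seed = 1, frac_excluded_types = 0))
  res <- calibrate_theta(sim$baseline$saturation, survey,
                         theta_grid_step = 0.01, n_bootstrap = 100, seed = 1)
  expect_lte(abs(res$theta_star - 0.48), 0.01)
  expect_equal(res$pod_calibration, 1)
  expect_gte(res$pod_validation, 0.95)
})

test_that("calibration is deterministic and validates its arguments", {
  sim <- default_sim()
  survey <- filter_survey(make_survey(sim$baseline$saturation, sim$domain,
                                      theta_true = 0.48, n_points = 40,
                                      seed = 2))
  r1 <- calibrate_theta(sim$baseline$saturation, survey, n_bootstrap = 20,
                        seed = 9)
  r2 <- calibrate_theta(sim$baseline$saturation, survey, n_bootstrap = 20,
                        seed = 9)
  expect_identical(r1$theta_star, r2$theta_star)
  expect_identical(r1$bootstrap_thetas, r2$bootstrap_thetas)
  expect_error(calibrate_theta(sim$baseline$saturation, survey,
                               theta_grid_step = 0.6), "theta_grid_step")
  expect_error(calibrate_theta(sim$baseline$saturation, survey,
                               n_bootstrap = 0), "n_bootstrap")
})

test_that("synthetic surveys pond where claimed and honour exclusions", {
  sim <- default_sim()
  survey <- make_survey(sim$baseline$saturation, sim$domain,
                        theta_true = 0.48, n_points = 102, seed = 1,
                        frac_excluded_types = 0)
  expect_equal(nrow(survey), 102)
  rainy <- pondwi:::period_index(sim$baseline$saturation$dates, "RAINY")
  max_s <- apply(sim$baseline$saturation$values[, , rainy], c(1, 2), max)
  expect_true(all(max_s[cbind(survey$row, survey$col)] >= 0.48))
  # at least one anchor within one grid step of the planted threshold
  expect_true(any(max_s[cbind(survey$row, survey$col)] < 0.49))

  all_excluded <- make_survey(sim$baseline$saturation, sim$domain,
                              theta_true = 0.48, n_points = 30, seed = 1,
                              frac_excluded_types = 1)
  expect_error(filter_survey(all_excluded), "no usable survey points")

  dry <- sim$baseline$saturation
  dry$values <- dry$values * 0.5
  expect_error(make_survey(dry, sim$domain, theta_true = 0.9, n_points = 5,
                           seed = 1), "unpondable domain")
})
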