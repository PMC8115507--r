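test_that("stream masking counts exceedance days correctly", {
  still <- toy_cube(array(0, dim = c(4, 4, 365)), cls = "flow_cube")
  expect_true(all(!stream_mask(still)))
  fast <- toy_cube(array(0.02, dim = c(4, 4, 365)), cls = "flow_cube")
  expect_true(all(stream_mask(fast)))

  set.seed(12)
  q <- array(rgamma(4 * 4 * 365, 0.3, scale = 0.05), dim = c(4, 4, 365))
  flow <- toy_cube(q, cls = "flow_cube")
  brute <- apply(q, c(1, 2), function(v) mean(v > 0.01) >= 0.9)
  expect_identical(stream_mask(flow), brute)
})

test_that("exceedance probability matches the closed form and brute force", {
  wet <- compute_wi(toy_cube(array(0.9, dim = c(2, 2, 365))), 0.48)
  p10 <- exceedance_probability(wet, 10, "YEAR")
  expect_equal(p10$values[1, 1], 355 / 365)
  p15 <- exceedance_probability(wet, 15, "YEAR")
  expect_equal(p15$values[1, 1], 350 / 365)

  zero <- toy_cube(array(0L, dim = c(2, 2, 365)), cls = "wetness_cube")
  expect_true(all(exceedance_probability(zero, 10, "YEAR")$values == 0))

  sat <- random_sat_cube(8, 8, 365, seed = 21)
  wi <- compute_wi(sat, 0.6)
  m <- as.integer(format(wi$dates, "%m"))
  for (period in c("YEAR", "DRY", "RAINY")) {
    months <- pondwi:::period_months(period)
    brute <- apply(wi$values[, , m %in% months], c(1, 2),
                   function(v) mean(v > 10))
    expect_equal(exceedance_probability(wi, 10, period)$values, brute)
  }
})

test_that("year counts decompose exactly into dry plus rainy counts", {
  sat <- random_sat_cube(10, 10, 365, seed = 33)
  wi <- compute_wi(sat, 0.55)
  m <- as.integer(format(wi$dates, "%m"))
  n_dry <- sum(m %in% c(1:4, 11:12)); n_rainy <- sum(m %in% 5:10)
  py <- exceedance_probability(wi, 10, "YEAR")$values
  pd <- exceedance_probability(wi, 10, "DRY")$values
  pr <- exceedance_probability(wi, 10, "RAINY")$values
  expect_equal(py * 365, pd * n_dry + pr * n_rainy, tolerance = 1e-12)
})

test_that("stricter duration thresholds are nested", {
  sat <- random_sat_cube(10, 10, 365, seed = 44)
  wi <- compute_wi(sat, 0.5)
  p10 <- exceedance_probability(wi, 10, "YEAR")$values
  p15 <- exceedance_probability(wi, 15, "YEAR")$values
  expect_true(all(p15 <= p10))
  region <- matrix(TRUE, 10, 10)
  f10 <- coverage_series(wi, 10, region)$F
  f15 <- coverage_series(wi, 15, region)$F
  expect_true(all(f15 <= f10))
})

test_that("masked cells are missing, not zero, and periods validate", {
  wi <- compute_wi(random_sat_cube(4, 4, 365, seed = 2), 0.5)
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE
  p <- exceedance_probability(wi, 10, "YEAR", mask = mask)
  expect_true(is.na(p$values[1, 1]))
  expect_true(p$mask_applied)
  expect_error(exceedance_probability(wi, 0, "YEAR"), "T must be")
})

test_that("daily coverage counts region cells with the chosen comparator", {
  wi <- toy_cube(array(c(11L, 0L, 20L, 3L), dim = c(2, 2, 1)),
                 cls = "wetness_cube")
  region <- matrix(TRUE, 2, 2)
  expect_equal(coverage_series(wi, 10, region)$F, 0.5)
  expect_equal(coverage_series(wi, 11, region)$F, 0.25)          # strict
  expect_equal(coverage_series(wi, 11, region, "geq")$F, 0.5)
  # T = 0 with the strict comparator: fraction currently ponded
  expect_equal(coverage_series(wi, 0, region)$F, 0.75)

  sat <- random_sat_cube(6, 6, 100, seed = 10)
  w <- compute_wi(sat, 0.5)
  cells <- which(matrix(runif(36) < 0.5, 6, 6))
  flat <- matrix(w$values, 36, 100)
  brute <- colMeans(flat[cells, , drop = FALSE] > 7)
  expect_equal(coverage_series(w, 7, cells)$F, brute)
  expect_error(coverage_series(w, 7, integer(0)), "region_cells")
})

test_that("monthly summaries report means, CIs, and partial months", {
  dates <- make_dates(2018)
  f <- structure(data.frame(date = dates, F = rep(0.5, 365)),
                 class = c("coverage_series", "data.frame"))
  m <- monthly_mean_coverage(f)
  expect_equal(nrow(m), 12)
  expect_true(all(m$mean == 0.5))
  expect_true(all(m$ci_high - m$ci_low == 0))
  expect_equal(m$n_days[m$month == 1], 31)
  expect_false(any(m$partial))

  alt <- structure(data.frame(date = dates[1:30], F = rep(c(0, 1), 15)),
                   class = c("coverage_series", "data.frame"))
  ma <- monthly_mean_coverage(alt)
  expect_equal(ma$mean, 0.5)
  expect_equal(ma$ci_high - ma$ci_low, 2 * 1.96 * 0.5085476 / sqrt(30),
               tolerance = 1e-4)
  expect_true(ma$partial)   # January cut at 30 of 31 days
})

test_that("stability classes follow the duration boundaries", {
  dur <- matrix(c(0, 14, 15, 89, 90, 179, 180, 365, 400), 3, 3)
  s <- classify_stability(dur)
  expect_equal(as.vector(s$class),
               c("NON_HABITAT", "NON_HABITAT", "TEMPORARY", "TEMPORARY",
                 "SEMI_PERMANENT", "SEMI_PERMANENT", "PERMANENT", "PERMANENT",
                 "PERMANENT"))
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  expect_equal(sum(s$histogram$fraction), 1, tolerance = 1e-12)
  # final bin is open: both 365 and 400 land in [360, Inf)
  expect_equal(s$histogram$count[s$histogram$bin_start == 360], 2)
  expect_error(classify_stability(matrix(-1, 1, 1)), "non-negative")
})

test_that("stability fractions match brute-force binning under masking", {
  set.seed(50)
  dur <- matrix(sample(0:400, 400, TRUE), 20, 20)
  mask <- matrix(runif(400) < 0.2, 20, 20)
  s <- classify_stability(dur, mask)
  expect_true(all(is.na(s$class[mask])))
  d <- dur[!mask]
  expect_equal(unname(s$fractions),
               c(mean(d < 15), mean(d >= 15 & d < 90),
                 mean(d >= 90 & d < 180), mean(d >= 180)))
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
})
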