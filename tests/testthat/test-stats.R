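toy_map <- function(values, T = 10, period = "YEAR", scen = "x") {
  structure(list(values = values, T = T, period = period,
                 scenario_label = scen, mask_applied = FALSE),
            class = "exceedance_map")
}

test_that("scenario summaries report interpolated quantiles", {
  const <- toy_map(matrix(0.4, 4, 4))
  rows <- summarize_exceedance(const, const, matrix(TRUE, 4, 4))
  expect_equal(rows$mean, c(0.4, 0.4))
  expect_equal(rows$p25, c(0.4, 0.4))
  expect_equal(rows$median, c(0.4, 0.4))
  expect_equal(rows$p75, c(0.4, 0.4))

  m <- toy_map(matrix(c(0, 0, 1, 1), 2, 2))
  r <- summarize_exceedance(m, m, matrix(TRUE, 2, 2))
  expect_equal(r$p25[1], 0)
  expect_equal(r$median[1], 0.5)
  expect_equal(r$p75[1], 1)
  expect_identical(r[1, c("mean", "p25", "median", "p75")],
                   structure(r[2, c("mean", "p25", "median", "p75")],
                             row.names = 1L))

  set.seed(3)
  v <- matrix(runif(64), 8, 8)
  r2 <- summarize_exceedance(toy_map(v), toy_map(v), matrix(TRUE, 8, 8))
  sorted <- sort(as.vector(v))
  expect_equal(r2$median[1], median(sorted))
  expect_equal(r2$p25[1], quantile(sorted, 0.25, names = FALSE))
  expect_error(summarize_exceedance(toy_map(matrix(NA_real_, 2, 2)),
                                    toy_map(matrix(NA_real_, 2, 2)),
                                    matrix(TRUE, 2, 2)), "empty")
})

test_that("rank-sum p-value matches exact enumeration on small samples", {
  b <- c(1, 2, 3); i <- c(4, 5, 6)
  res <- wilcoxon_increase_test(b, i)
  # enumeration oracle: rank sum of the 'irrigation' labels over all
  # C(6,3) = 20 assignments of the pooled values
  pooled <- c(b, i)
  obs <- sum(rank(pooled)[4:6])
  combos <- utils::combn(6, 3)
  null_sums <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
  p_exact <- mean(null_sums >= obs)
  expect_equal(p_exact, 0.05)
  expect_equal(res$p_value, p_exact)
  expect_equal(res$method, "exact")
})

test_that("rank-sum direction and degeneracy behave", {
  x <- c(0.1, 0.4, 0.2, 0.8, 0.3)
  expect_gte(wilcoxon_increase_test(x, x + 1e-9 * 0)$p_value, 0.5)
  expect_gt(wilcoxon_increase_test(c(10, 11, 12), c(1, 2, 3))$p_value, 0.9)
  deg <- wilcoxon_increase_test(rep(0.2, 5), rep(0.2, 7))
  expect_equal(deg$p_value, 0.5)
  expect_true(deg$degenerate)
  expect_error(wilcoxon_increase_test(numeric(0), 1), "non-empty")
})

test_that("exact and approximate rank-sum p-values agree for small n", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(3:10, 1); m <- sample(3:10, 1)
    b <- rnorm(n); i <- rnorm(m, mean = runif(1, -1, 1))
    pe <- wilcoxon_increase_test(b, i, exact = TRUE)$p_value
    pa <- wilcoxon_increase_test(b, i, exact = FALSE)$p_value
    expect_lte(abs(pe - pa), 0.02)
  }
})

test_that("Welch test on monthly coverage matches the closed formula", {
  dates <- make_dates(2018)
  jan <- dates[1:31]
  set.seed(9)
  fb <- runif(31, 0.2, 0.4); fi <- fb + 0.05 + rnorm(31, 0, 0.02)
  mk <- function(d, f) structure(data.frame(date = d, F = f),
                                 class = c("coverage_series", "data.frame"))
  res <- monthly_coverage_test(mk(jan, fb), mk(jan, fi), 1)
  tt <- (mean(fi) - mean(fb)) / sqrt(var(fi) / 31 + var(fb) / 31)
  expect_equal(res$t_stat, tt, tolerance = 1e-12)
  df <- (var(fi) / 31 + var(fb) / 31)^2 /
    ((var(fi) / 31)^2 / 30 + (var(fb) / 31)^2 / 30)
  expect_equal(res$p_value, pt(tt, df, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("Welch test flags shifts and handles identical or constant series", {
  dates <- make_dates(2018)[1:31]
  mk <- function(f) structure(data.frame(date = dates, F = f),
                              class = c("coverage_series", "data.frame"))
  set.seed(11)
  base <- runif(31, 0.3, 0.35)
  expect_true(monthly_coverage_test(mk(base), mk(base + 0.3), 1)$significant_at_0.01)
  same <- monthly_coverage_test(mk(base), mk(base), 1)
  expect_false(same$significant_at_0.01)
  deg <- monthly_coverage_test(mk(rep(0.5, 31)), mk(rep(0.5, 31)), 1)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0.5)
  expect_error(monthly_coverage_test(mk(base), mk(base), 13), "not covered")
})
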