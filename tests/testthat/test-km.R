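test_that("product-limit estimate matches hand computations", {
  km <- km_estimate(tibble::tibble(time_months = c(1, 2, 3),
                                   event = c(TRUE, TRUE, TRUE)))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # censoring at 2 removes that patient from later risk sets
  km2 <- km_estimate(tibble::tibble(time_months = c(1, 2, 3),
                                    event = c(TRUE, FALSE, TRUE)))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$n_risk, c(3L, 1L))
  expect_equal(km2$survival, c(2 / 3, 0))

  all_cens <- km_estimate(tibble::tibble(time_months = c(1, 5, 9),
                                         event = rep(FALSE, 3)))
  expect_equal(nrow(all_cens), 0)
  expect_equal(death_rate_at(all_cens, 4), 0, ignore_attr = TRUE)
})

test_that("deaths are processed before censorings at tied times", {
  km <- km_estimate(tibble::tibble(time_months = c(2, 2, 2, 5),
                                   event = c(TRUE, FALSE, TRUE, TRUE)))
  # both deaths at t = 2 see all 4 at risk (the censored record included)
  expect_equal(km$n_risk[1], 4L)
  expect_equal(km$survival[1], 0.5)
})

test_that("with no censoring the estimate equals the empirical survivor function", {
  for (seed in 1:5) {
    times <- withr::with_seed(seed, round(rexp(60, 0.2), 2))
    km <- km_estimate(tibble::tibble(time_months = times, event = TRUE))
    probe <- c(0, sort(unique(times)), max(times) + 1)
    est <- vapply(probe, function(h) {
      i <- which(km$time <= h)
      if (length(i)) km$survival[max(i)] else 1
    }, double(1))
    expect_equal(est, empirical_survivor(times, probe))
  }
})

test_that("estimate and Greenwood errors agree with the survival package", {
  co <- simulate_cohort(cohort_config(n = 300, seed = 14))
  km <- km_estimate(co)
  ref <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = co)
  at_events <- summary(ref, times = km$time)
  expect_equal(km$survival, at_events$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, at_events$n.risk, ignore_attr = TRUE)
  expect_equal(km$std_err, at_events$std.err, tolerance = 1e-8)
})

test_that("death_rate_at is definitional, right-continuous and monotone", {
  km <- km_estimate(tibble::tibble(
    time_months = c(0.5, 1, 1, 2, 3, 4, 6),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)))
  expect_equal(death_rate_at(km, 0), 0, ignore_attr = TRUE)
  # deaths exactly at the horizon count as dead
  expect_equal(death_rate_at(km, 0.5), 100 * (1 - 6 / 7), ignore_attr = TRUE)
  h <- seq(0, 6, by = 0.25)
  rates <- suppressWarnings(as.numeric(death_rate_at(km, h)))
  expect_true(all(diff(rates) >= 0))
  expect_true(all(rates >= 0 & rates <= 100))
})

test_that("horizons beyond follow-up return the last estimate and flag extrapolation", {
  km <- km_estimate(tibble::tibble(time_months = c(1, 2, 3),
                                   event = c(TRUE, TRUE, FALSE)))
  expect_warning(r <- death_rate_at(km, 10), "extrapolat")
  expect_equal(as.numeric(r), 100 * (1 - 1 / 3))
  expect_true(attr(r, "extrapolated"))
})

test_that("planted-rate curves recover the planted death rate", {
  co <- planted_rate_cohort(c(x = 0.15), n_per_level = 20000, horizon = 1,
                            seed = 9)
  km <- km_estimate(co)
  se_pct <- 100 * sqrt(0.15 * 0.85 / 20000)
  expect_lt(abs(as.numeric(death_rate_at(km, 1)) - 15), 3 * se_pct)
})

test_that("median survival is definitional and recovers the exponential median", {
  km <- km_estimate(tibble::tibble(time_months = c(8.6, 9), event = TRUE))
  expect_equal(median_survival(km), 8.6)  # S drops to exactly 0.5 at 8.6
  all_cens <- km_estimate(tibble::tibble(time_months = 1:4, event = FALSE))
  expect_true(is.na(median_survival(all_cens)))

  m <- 7
  times <- withr::with_seed(13, rexp(5000, log(2) / m))
  km2 <- km_estimate(tibble::tibble(time_months = times, event = TRUE))
  tol <- 3 * m / (log(2) * sqrt(5000))
  expect_lt(abs(median_survival(km2) - m), tol)
})

test_that("curve invariants hold on simulated cohorts", {
  for (seed in 1:5) {
    co <- simulate_cohort(cohort_config(n = 150, seed = 100 + seed))
    km <- km_estimate(co)
    expect_true(all(diff(km$time) > 0))
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    expect_true(all(diff(km$n_risk) <= 0))
    expect_true(all(km$n_event <= km$n_risk))
    expect_identical(attr(km, "n0"), nrow(co))
  }
})

test_that("empty input is an error", {
  expect_error(km_estimate(tibble::tibble(time_months = double(),
                                          event = logical())),
               class = "reradscore_validation_error")
  expect_error(km_estimate(tibble::tibble(time_months = -1, event = TRUE)),
               class = "reradscore_validation_error")
})
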