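test_that("quantile-line fit matches the brute-force pair-enumeration oracle", {
  set.seed(21)
  for (case in 1:5) {
    n <- sample(60:200, 1)
    x <- seq_len(n)
    y <- switch(1 + case %% 3,
                0.4 + 0.002 * x + pmax(0, sin(pi * (x %% 24 - 6) / 12)) * 3 +
                  rnorm(n, 0, 0.1),
                rnorm(n),
                2 - 0.01 * x + rexp(n, 1))
    fit <- fit_quantile_line(x, y, tau = 0.1)
    expect_equal(fit$objective, oracle_quantile_line(x, y, 0.1),
                 tolerance = 1e-8)
    # and at the 0.5 level for good measure
    fit5 <- fit_quantile_line(x, y, tau = 0.5)
    expect_equal(fit5$objective, oracle_quantile_line(x, y, 0.5),
                 tolerance = 1e-8)
  }
})

test_that("baseline correction recovers a planted drift within 2%", {
  ts <- seq(as.POSIXct("2023-05-01", tz = "UTC"),
            as.POSIXct("2023-05-31 23:45", tz = "UTC"), by = "15 min")
  h <- as.numeric(difftime(ts, ts[1], units = "hours"))
  hod <- as.integer(format(ts, "%H"))
  drift <- 3e-4
  raw <- 0.8 + drift * h + pmax(0, sin(pi * (hod - 6) / 12)) * 6
  bc <- baseline_correct(data.frame(timestamp = ts, sap_flow_kg_h = raw))
  expect_equal(bc$slope, drift, tolerance = 0.02)
  # fixed point: refitting the tau = 0.1 line on the corrected series is flat
  refit <- fit_quantile_line(
    as.numeric(difftime(bc$series$timestamp, bc$series$timestamp[1],
                        units = "hours")), bc$series$corrected, 0.1)
  expect_lt(abs(refit$slope), 1e-6)
  expect_lt(abs(refit$intercept), 1e-6)
})

test_that("baseline correction zeroes a constant series and is idempotent", {
  ts <- seq(as.POSIXct("2023-05-01", tz = "UTC"),
            as.POSIXct("2023-05-31 23:00", tz = "UTC"), by = "hour")
  bc <- baseline_correct(data.frame(timestamp = ts,
                                    sap_flow_kg_h = rep(2.5, length(ts))))
  expect_equal(bc$series$corrected, rep(0, length(ts)))
  set.seed(9)
  noisy <- data.frame(timestamp = ts,
                      sap_flow_kg_h = 1 + 1e-4 * seq_along(ts) +
                        rexp(length(ts), 2))
  b1 <- baseline_correct(noisy)
  scale <- diff(range(noisy$sap_flow_kg_h))
  b2 <- baseline_correct(data.frame(timestamp = b1$series$timestamp,
                                    sap_flow_kg_h = b1$series$corrected))
  expect_lt(max(abs(b2$series$corrected - b1$series$corrected)), 1e-6 * scale)
  # roughly 10% of corrected hourly values sit below the fitted line
  expect_equal(mean(b1$series$corrected < 0), 0.1, tolerance = 0.5)
  expect_error(baseline_correct(noisy[1:50, ]), "too short")
})

test_that("per-circumference flux follows the sapwood-circumference equation", {
  expect_equal(sf_per_circumference(10, 100, 0), 0.1)
  expect_equal(sf_per_circumference(10, 100, 1), 10 / (100 - 2 * pi),
               tolerance = 1e-12)
  expect_equal(round(sf_per_circumference(10, 100, 1), 4), 0.1067)
  expect_equal(sf_per_circumference(20, 100, 1),
               2 * sf_per_circumference(10, 100, 1))
  expect_error(sf_per_circumference(10, 6, 1), "2\\*pi")
})

test_that("daily aggregation pins the quantile type and flags partial days", {
  ts <- as.POSIXct("2023-06-01", tz = "UTC") + 3600 * (0:23)
  d <- daily_aggregate(data.frame(timestamp = ts, corrected = rep(3, 24)))
  expect_equal(d$q90, 3)
  expect_equal(d$daily_sum, 72)
  vals <- sample(1:24)
  d <- daily_aggregate(data.frame(timestamp = ts, corrected = vals))
  expect_equal(d$q90, oracle_q_type7(vals, 0.9), tolerance = 1e-12)
  # a day with < 80% of slots is flagged and masked
  d <- daily_aggregate(data.frame(timestamp = ts[1:10], corrected = 1:10))
  expect_false(d$valid)
  expect_true(is.na(d$q90) && is.na(d$daily_sum))
})

test_that("daily statistics are invariant to a consistent whole-day shift", {
  set.seed(14)
  ts <- seq(as.POSIXct("2023-06-01", tz = "UTC"), by = "hour",
            length.out = 24 * 40)
  v <- rexp(length(ts)) + pmax(0, sin(pi * (as.integer(format(ts, "%H")) - 6) / 12))
  d1 <- daily_aggregate(data.frame(timestamp = ts, corrected = v))
  d2 <- daily_aggregate(data.frame(timestamp = ts + 86400 * 3, corrected = v))
  expect_equal(d1$q90, d2$q90)
  expect_equal(d1$daily_sum, d2$daily_sum)
  expect_equal(d2$date, d1$date + 3)
})

test_that("reduction from the annual maximum recovers a planted dip", {
  daily <- data.frame(date = as.Date("2023-01-01") + 0:364,
                      q90 = 10, daily_sum = 100,
                      completeness = 1, valid = TRUE)
  dip_days <- 180:260
  daily$q90[dip_days] <- 7   # a 30% dry-season dip
  r <- reduction_from_annual_max(daily)
  expect_equal(r$reduction_pct[1], 0)
  expect_equal(mean(r$reduction_pct[dip_days]), 30, tolerance = 1e-9)
  daily$q90[5] <- 5
  expect_equal(reduction_from_annual_max(daily)$reduction_pct[5], 50)
  short <- daily[1:10, ]
  expect_error(reduction_from_annual_max(short), "valid days")
})
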