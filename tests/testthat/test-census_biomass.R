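test_that("outlier filter agrees with a brute-force mean/sd oracle", {
  # the verdict comes from the oracle, not a hard-coded outcome
  vals <- c(1, 1, 1, 1, 50)
  cen <- make_census("t1", as.Date("2002-01-01") + (0:4) * 91, vals)
  res <- filter_growth_outliers(cen)
  removed_oracle <- abs(vals - mean(vals)) > 3 * sd(vals)
  expect_equal(is.na(res$census$circumference_increment_cm), removed_oracle)
  expect_equal(nrow(res$removals), sum(removed_oracle))
})

test_that("all-equal increments survive the strict 3-sd inequality", {
  cen <- make_census("t1", as.Date("2002-01-01") + (0:5) * 91, rep(0.2, 6))
  res <- filter_growth_outliers(cen)
  expect_false(anyNA(res$census$circumference_increment_cm))
  expect_equal(nrow(res$removals), 0L)
})

test_that("filter removes planted spikes and keeps false removals near the normal tail", {
  set.seed(42)
  n <- 10000
  x <- rnorm(n, 1, 0.1)
  spike_at <- sample(n, 30)
  x[spike_at] <- x[spike_at] + 10
  cen <- make_census("t1", as.Date("2002-01-01") + seq_len(n), x)
  res <- filter_growth_outliers(cen)
  expect_true(all(spike_at %in% which(is.na(res$census$circumference_increment_cm))))
  # clean data: false-removal rate approximately P(|Z| > 3) = 0.0027
  cen2 <- make_census("t2", as.Date("2002-01-01") + seq_len(n), rnorm(n, 1, 0.1))
  res2 <- filter_growth_outliers(cen2)
  rate <- nrow(res2$removals) / n
  expect_gt(rate, 0.0005)
  expect_lt(rate, 0.006)
})

test_that("short series pass through with a warning and empty input stays empty", {
  cen <- make_census("t1", as.Date("2002-01-01") + 0:1, c(1, 100))
  expect_warning(res <- filter_growth_outliers(cen), "unfiltered")
  expect_false(anyNA(res$census$circumference_increment_cm))
  empty <- make_census(character(), as.Date(character()), numeric())
  expect_equal(nrow(filter_growth_outliers(empty)$census), 0L)
})

test_that("DBH trajectory divides circumference growth by pi", {
  cen <- make_census("t1", as.Date(c("2002-01-01", "2002-04-01", "2002-07-01",
                                     "2002-10-01")), rep(pi / 4, 4))
  tr <- dbh_trajectory(cen, c(t1 = 10))
  expect_equal(tr$dbh, 11)
  # 4 quarters of 0.5 cm on a 20 cm tree
  cen <- make_census("t1", as.Date(c("2002-01-01", "2002-04-01", "2002-07-01",
                                     "2002-10-01")), rep(0.5, 4))
  tr <- dbh_trajectory(cen, c(t1 = 20))
  expect_equal(tr$dbh, 20 + 2 / pi, tolerance = 1e-12)
  expect_equal(tr$completeness, 1)
})

test_that("zero growth and missing years leave DBH constant with flags", {
  dates <- as.Date(c("2002-01-01", "2002-04-01", "2004-01-01"))
  cen <- make_census("t1", dates, c(0, 0, 0))
  tr <- dbh_trajectory(cen, c(t1 = 15), years = 2002:2004)
  expect_equal(tr$dbh, rep(15, 3))
  expect_equal(tr$completeness, c(0.5, 0, 0.25))
})

test_that("plot aggregation equals an independently coded allometry oracle", {
  set.seed(11)
  n <- 300
  stand <- data.frame(
    tree_id = sprintf("s%03d", 1:n), plot = "control",
    genus = sample(c("A", "B"), n, TRUE),
    wood_density = runif(n, 0.3, 0.9), wood_density_se = runif(n, 0, 0.08),
    initial_dbh = runif(n, 10, 120))
  traj <- data.frame(tree_id = stand$tree_id, year = 2002,
                     dbh = stand$initial_dbh)
  agg <- aggregate_plot(stand, traj, 2002)
  expect_equal(agg$agb_mean,
               sum(oracle_tree_mgc(stand$initial_dbh, stand$wood_density)),
               tolerance = 1e-9)
  # CI ordering survives aggregation, and totals are additive:
  expect_true(agg$agb_lo <= agg$agb_mean && agg$agb_mean <= agg$agb_hi)
  big <- stand$tree_id[which.max(stand$initial_dbh)]
  agg2 <- aggregate_plot(stand, traj, 2002,
                         alive_ids = setdiff(stand$tree_id, big))
  expect_equal(agg$agb_mean - agg2$agb_mean,
               oracle_tree_mgc(max(stand$initial_dbh),
                               stand$wood_density[stand$tree_id == big]),
               tolerance = 1e-9)
  # permutation invariance in tree order
  perm <- sample(n)
  agg3 <- aggregate_plot(stand[perm, ], traj[perm, ], 2002)
  expect_equal(agg3$agb_mean, agg$agb_mean, tolerance = 1e-12)
})

test_that("annual biomass change handles gap years and telescopes", {
  s <- data.frame(plot = "TFE", year = c(2015, 2016), agb_mean = c(170, 168))
  expect_equal(delta_biomass(s)$delta_biomass, c(NA, -2))
  s <- data.frame(plot = "TFE", year = c(2020, 2022), agb_mean = c(150, 154))
  expect_equal(delta_biomass(s)$delta_biomass, c(NA, 2))
  set.seed(3)
  s <- data.frame(plot = "x", year = sort(sample(2002:2023, 12)),
                  agb_mean = runif(12, 150, 260))
  d <- delta_biomass(s)
  expect_equal(sum(d$delta_biomass * d$year_gap, na.rm = TRUE),
               s$agb_mean[12] - s$agb_mean[1], tolerance = 1e-12)
})

test_that("canopy classification puts the 30 cm boundary in the subcanopy", {
  expect_equal(classify_canopy(c(10, 30, 30.1, 85)),
               c("subcanopy", "subcanopy", "topcanopy_emergent",
                 "topcanopy_emergent"))
})

test_that("percent biomass change reproduces the worked example", {
  expect_equal(round(percent_biomass_change(248, 85)), 34)
  expect_equal(percent_biomass_change(200, 0), 0)
  expect_equal(percent_biomass_change(200, 200), 100)
  expect_error(percent_biomass_change(0, 10), "positive")
})
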