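test_that("the generator is bit-identical under a fixed seed", {
  cfg <- small_config(seed = 5)
  s1 <- simulate_scenario(cfg, soil_resolution = "daily", hydraulics = FALSE)
  s2 <- simulate_scenario(cfg, soil_resolution = "daily", hydraulics = FALSE)
  expect_identical(s1$stand, s2$stand)
  expect_identical(s1$census, s2$census)
  expect_identical(s1$soil, s2$soil)
  expect_identical(s1$truth$death_year, s2$truth$death_year)
})

test_that("an empty stand and invalid configurations are handled", {
  cfg <- scenario_config(n_trees_per_plot = 0)
  gs <- generate_stand(cfg)
  expect_equal(nrow(gs$stand), 0L)
  expect_length(gs$truth, 0L)
  expect_error(scenario_config(throughfall_exclusion_fraction = 1.2),
               "\\[0, 1\\]")
  expect_error(scenario_config(dbh_range = c(5, 160)), "10 cm")
  gp <- default_genus_pool(); gp$wood_density[1] <- -0.1
  expect_error(scenario_config(genus_pool = gp), "positive")
})

test_that("stand draws respect the genus pool, DBH bounds and matched composition", {
  cfg <- scenario_config(n_trees_per_plot = 300, seed = 3)
  st <- generate_stand(cfg)$stand
  expect_true(all(st$genus %in% default_genus_pool()$genus))
  expect_true(all(st$initial_dbh >= 10 & st$initial_dbh <= 160))
  expect_equal(table(st$genus[st$plot == "control"]),
               table(st$genus[st$plot == "TFE"]))
})

test_that("census plants the configured spike load and stops at death", {
  cfg <- scenario_config(n_trees_per_plot = 200, years = 2002:2012,
                         gap_years = integer(), spike_rate = 0.02, seed = 9)
  sim <- simulate_scenario(cfg, soil_resolution = "daily", hydraulics = FALSE)
  n_inc <- nrow(sim$census)
  n_spikes <- nrow(sim$truth$spikes)
  expect_equal(n_spikes / n_inc, 0.02, tolerance = 0.25)
  dead <- sim$truth$death_year[!is.na(sim$truth$death_year)]
  for (id in names(dead)[1:min(10, length(dead))]) {
    obs_years <- as.integer(format(sim$census$date[sim$census$tree_id == id],
                                   "%Y"))
    if (length(obs_years)) expect_lt(max(obs_years), dead[[id]])
  }
  # no spikes planted when the rate is zero
  cfg0 <- small_config(seed = 9, spike_rate = 0)
  sim0 <- simulate_scenario(cfg0, soil_resolution = "daily",
                            hydraulics = FALSE)
  expect_null(sim0$truth$spikes)
})

test_that("the 3-sd filter recovers planted spikes at high recall", {
  cfg <- scenario_config(n_trees_per_plot = 150, years = 2002:2012,
                         gap_years = integer(), spike_rate = 0.02,
                         spike_magnitude = 20, seed = 13)
  sim <- simulate_scenario(cfg, soil_resolution = "daily", hydraulics = FALSE)
  res <- suppressWarnings(filter_growth_outliers(sim$census))
  planted <- paste(sim$truth$spikes$tree_id, sim$truth$spikes$date)
  caught <- paste(res$removals$tree_id, res$removals$date)
  expect_gte(mean(planted %in% caught), 0.95)
})

test_that("throughfall exclusion scales water input exactly", {
  cfg <- small_config(seed = 2)
  sm <- simulate_soil_moisture(cfg, resolution = "daily")
  in_ratio <- sum(sm$truth$TFE$annual$input) /
    sum(sm$truth$control$annual$input)
  expect_equal(in_ratio, 0.5, tolerance = 1e-12)
  # no exclusion: the two plots are identical
  cfg0 <- small_config(seed = 2, throughfall_exclusion_fraction = 0)
  sm0 <- simulate_soil_moisture(cfg0, resolution = "daily")
  w <- reshape(sm0$soil, direction = "wide", idvar = c("timestamp", "depth_m"),
               timevar = "plot")
  expect_equal(w$vwc.control, w$vwc.TFE)
})

test_that("constant-theta mode emits a flat profile", {
  cfg <- small_config(seed = 2)
  sm <- simulate_soil_moisture(cfg, resolution = "daily",
                               constant_theta = 0.3)
  expect_true(all(sm$soil$vwc == 0.3))
  expect_equal(sm$truth$total_water_mm, 1200)
})

test_that("the soil bucket conserves water to machine precision", {
  cfg <- small_config(seed = 4)
  sm <- simulate_soil_moisture(cfg, resolution = "daily")
  for (pl in c("control", "TFE")) {
    tr <- sm$truth[[pl]]
    d <- tr$daily
    lhs <- sum(d$input) - sum(d$uptake) - sum(d$drainage)
    rhs <- d$storage[nrow(d)] - tr$initial_storage
    expect_equal(lhs, rhs, tolerance = 1e-6 * max(1, abs(rhs)))
  }
})

test_that("daily-mean soil totals recover the bucket storage exactly", {
  cfg <- small_config(seed = 6, years = 2002:2003)
  sm <- simulate_soil_moisture(cfg, resolution = "hourly")
  tot <- soil_total_water(sm$soil)
  am <- annual_max_water(tot)
  for (pl in c("control", "TFE"))
    expect_equal(am$max_total_water_mm[am$plot == pl],
                 sm$truth[[pl]]$annual$max_storage, tolerance = 1e-9)
})

test_that("night-time sap flow sits at the sensor baseline", {
  cfg <- small_config(seed = 7)
  st <- generate_stand(cfg)
  hy <- simulate_hydraulics(st$stand, NULL, cfg, streams = "sapflow",
                            year = 2008)
  one <- hy$sapflow[hy$sapflow$tree_id == hy$trees$tree_id[1], ]
  hod <- as.integer(format(one$timestamp, "%H"))
  night <- one$sap_flow_kg_h[hod < 5 | hod > 19]
  h <- as.numeric(difftime(one$timestamp, one$timestamp[1], units = "hours"))
  baseline <- hy$truth$baseline_offset[[1]] +
    hy$truth$baseline_drift[[1]] * h[hod < 5 | hod > 19]
  resid <- night - baseline
  expect_lt(abs(mean(resid)), 0.05 * hy$truth$amplitude[[1]])
})

test_that("the stem-VWC stream carries the recoverable temperature artifact", {
  cfg <- small_config(seed = 8)
  st <- generate_stand(cfg)
  hy <- simulate_hydraulics(st$stand, NULL, cfg, streams = "stem_vwc",
                            year = 2008)
  one <- hy$stem_vwc[hy$stem_vwc$tree_id == hy$trees$tree_id[1], ]
  one <- one[as.integer(format(one$timestamp, "%j")) <= 60, ]
  b_hat <- estimate_temperature_effect(one$vwc_raw, one$temperature,
                                       one$timestamp)
  expect_equal(b_hat, -0.000974, tolerance = 0.05)
})

test_that("campaign tables respect tissue-mass ordering and tension signs", {
  cfg <- small_config(seed = 10)
  st <- generate_stand(cfg)
  hy <- simulate_hydraulics(st$stand, NULL, cfg, streams = "campaigns")
  expect_true(all(hy$leaf_wp$wp_mpa < 0))
  lt <- hy$leaf_tissue
  expect_true(all(lt$m_dry <= lt$m_fresh & lt$m_fresh <= lt$m_turgid))
  expect_true(all(hy$branch_tissue$v_fresh > 0))
  # replicate structure: 3 branches x 2 leaves x 2 times of day x 3 campaigns
  expect_equal(nrow(hy$leaf_wp), nrow(hy$trees) * 3 * 2 * 2 * 3)
})

test_that("scenario files round-trip through the plain-text sidecar format", {
  cfg <- small_config(seed = 12)
  sim <- simulate_scenario(cfg, soil_resolution = "daily", hydraulics = FALSE)
  dir <- tempfile("scenario")
  paths <- write_scenario(sim, dir)
  expect_true(all(file.exists(paths)))
  census <- read.csv(paths[["census"]])
  expect_equal(nrow(census), nrow(sim$census))
  truth <- jsonlite::read_json(paths[["ground_truth"]])
  expect_equal(length(truth$death_year), length(sim$truth$death_year))
  unlink(dir, recursive = TRUE)
})
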