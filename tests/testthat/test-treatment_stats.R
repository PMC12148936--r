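test_that("transform registry is total and follows the protocol rules", {
  responses <- c("q90", "daily_sum", "reduction_pct", "sapflow_reduction",
                 "wp_mpa", "leaf_wp_midday", "daily_max", "agb_mean",
                 "mean_growth", "rwc", "branch_vwc")
  rules <- vapply(responses, transform_for_response, character(1))
  expect_true(all(rules %in% c("log", "sqrt", "abs_then_log")))
  expect_equal(unname(rules[c("reduction_pct", "sapflow_reduction")]),
               c("sqrt", "sqrt"))
  expect_equal(unname(rules[c("wp_mpa", "leaf_wp_midday")]),
               c("abs_then_log", "abs_then_log"))
  expect_equal(unname(rules["q90"]), "log")
  expect_equal(apply_transform(c(-2, -0.5), "abs_then_log"), log(c(2, 0.5)))
  expect_equal(apply_transform(4, "sqrt"), 2)
  expect_error(apply_transform(1, "cube"), "unknown transform")
})

test_that("variance explained isolates the generating factor", {
  set.seed(17)
  n <- 200
  genus <- sample(LETTERS[1:6], n, TRUE)
  gmeans <- setNames(rnorm(6, 10, 3), LETTERS[1:6])
  dbh <- runif(n, 10, 100)
  d <- data.frame(genus = genus, diameter = dbh,
                  from_genus = gmeans[genus] + rnorm(n, 0, 0.3),
                  noise = rnorm(n, 5, 1),
                  from_dbh = 0.2 * dbh)
  r <- variance_explained(d, "from_genus", transform = "none")
  expect_gt(r[["genus"]], 0.9)
  expect_lt(r[["diameter"]], 0.1)
  r <- variance_explained(d, "noise", transform = "none")
  expect_lt(max(r), 0.1)
  # exact linear response: lm warns about the perfect fit, R^2 is exactly 1
  r <- suppressWarnings(variance_explained(d, "from_dbh", transform = "none"))
  expect_equal(r[["diameter"]], 1, tolerance = 1e-9)
})

test_that("plot comparison model detects a large effect and reports structure", {
  p_null <- wp_plot_pvalue(101, effect = 0)
  p_big <- wp_plot_pvalue(101, effect = 2)
  expect_true(p_null >= 0 && p_null <= 1)
  expect_lt(p_big, 0.05)
  cfg <- small_config(seed = 101, hydraulic_effect_size = 0)
  st <- generate_stand(cfg)
  hy <- simulate_hydraulics(st$stand, NULL, cfg, streams = "campaigns")
  d <- hy$leaf_wp[hy$leaf_wp$time_of_day == "midday", ]
  res <- suppressWarnings(compare_plots(d, comparison_spec("wp_mpa")))
  expect_s3_class(res, "model_result")
  expect_equal(res$transform, "abs_then_log")
  expect_true(all(c("no_diameter", "no_genus") %in% names(res$reduced)))
  expect_true(is.logical(res$conclusions_converge))
  expect_gt(res$n_obs, length(res$terms$term))
})

test_that("null p-values are approximately uniform", {
  pvals <- vapply(1:200, wp_plot_pvalue, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("density-biomass model finds a built-in density effect", {
  set.seed(23)
  yrs <- 2002:2016
  dens <- round(420 + 60 * sin(seq_along(yrs)))  # density varies, but not with year
  series <- data.frame(plot = "TFE", year = yrs, n_trees = dens,
                       n_topcanopy = 40, n_subcanopy = dens - 40,
                       agb_mean = exp(3 + 0.004 * dens + rnorm(length(yrs), 0,
                                                               0.01)))
  r <- density_biomass_model(series, "total")
  expect_gt(r$slope, 0)
  expect_lt(r$p, 0.05)
  expect_true(r$significance_robust_to_year)
  # constant density is degenerate, flagged not fitted
  r2 <- density_biomass_model(series, "topcanopy")
  expect_true(r2$degenerate)
  expect_true(is.na(r2$slope))
  expect_error(density_biomass_model(series[1:3, ], "total"), ">= 5")
})

test_that("growth-water model recovers a linear dependence on rwa", {
  set.seed(29)
  yrs <- 2002:2020
  rwa <- data.frame(year = yrs, rwa_mean = seq(2.8, 4.2,
                                               length.out = length(yrs)))
  slope_true <- 0.5
  growth <- data.frame(year = yrs,
                       mean_growth = exp(-2 + slope_true * rwa$rwa_mean +
                                           rnorm(length(yrs), 0, 0.03)))
  r <- growth_water_model(growth, rwa)
  se <- abs(r$slope / qnorm(1 - r$p / 2))
  expect_lt(abs(r$slope - slope_true), 3 * se)
  expect_lt(r$p, 0.05)
  flat <- data.frame(year = yrs, rwa_mean = 3.5)
  r2 <- growth_water_model(growth, flat)
  expect_true(r2$degenerate)
})
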