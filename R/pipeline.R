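#' Phase summary of annual plot series
#'
#' Splits each plot's annual series at the changepoint year (transition
#' before, stabilization from the changepoint onward) and reports mean and
#' standard error of each value column per plot and phase. Phases with fewer
#' than two years get a missing s.e. and a flag.
#'
#' @param series data.frame with `plot`, `year` and one or more numeric
#'   columns to summarize.
#' @param changepoint_year first year of the stabilization phase (default
#'   2017).
#' @param columns columns to summarize (default: all numeric except `year`).
#' @return data.frame `plot`, `phase`, `variable`, `mean`, `se`, `n_years`,
#'   `flagged` (TRUE when n_years < 2).
#' @export
phase_summary <- function(series, changepoint_year = 2017, columns = NULL) {
  if (is.null(columns))
    columns <- setdiff(names(series)[vapply(series, is.numeric, logical(1))],
                       "year")
  phase <- ifelse(series$year < changepoint_year, "transition",
                  "stabilization")
  out <- list()
  for (pl in unique(series$plot)) for (ph in c("transition", "stabilization")) {
    s <- series[series$plot == pl & phase == ph, , drop = FALSE]
    for (v in columns) {
      x <- s[[v]][!is.na(s[[v]])]
      out[[paste(pl, ph, v)]] <- data.frame(
        plot = pl, phase = ph, variable = v,
        mean = if (length(x)) mean(x) else NA_real_,
        se = if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_,
        n_years = length(x), flagged = length(x) < 2)
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

# internal: require a stage to be enabled
need_stage <- function(stage, stages, for_what) {
  if (!stage %in% stages)
    stop("stage '", stage, "' is disabled but required by '", for_what, "'")
}

#' Run the end-to-end synthetic experiment pipeline
#'
#' Strings the stages together in the analysis order: scenario simulation,
#' census to annual plot biomass (with the outlier filter), soil-profile
#' integration to biomass-relative water availability, hydraulic stream
#' processing and mixed-model plot comparisons, phase summaries and the
#' basin-context sampling, and returns a report bundle with a stable,
#' versioned headline JSON structure.
#'
#' @param config a [scenario_config()].
#' @param stages stages to run; downstream stages fail fast, naming the
#'   missing stage, when a prerequisite is off.
#' @param changepoint_year first stabilization year (default 2017).
#' @param out_dir optional directory: per-stage CSVs plus `report.json` are
#'   written there.
#' @param soil_resolution resolution of the simulated soil series.
#' @param basin_n coordinates sampled per biome (default 10000).
#' @return A list with elements `biomass`, `delta`, `water`, `rwa`, `phases`,
#'   `hydraulic_tests`, `basin`, `report` (headline list), `truth`.
#' @export
run_pipeline <- function(config = scenario_config(),
                         stages = c("census", "soil", "hydraulics", "stats",
                                    "basin"),
                         changepoint_year = 2017,
                         out_dir = NULL,
                         soil_resolution = "hourly",
                         basin_n = 10000) {
  res <- list()
  report <- list(schema_version = "1.0", seed = config$seed,
                 changepoint_year = changepoint_year)
  need_stage("census", stages, "biomass")
  need_stage("soil", stages, "biomass-relative water availability")
  sim <- simulate_scenario(config, soil_resolution = soil_resolution,
                           hydraulics = "hydraulics" %in% stages)
  res$truth <- sim$truth

  # census -> annual biomass
  stand <- sim$stand
  stand$death_year <- sim$truth$death_year[stand$tree_id]
  biomass <- plot_biomass_series(sim$census, stand)
  delta <- delta_biomass(biomass)
  res$biomass <- biomass
  res$delta <- delta

  # soil -> annual max water -> rwa
  total <- soil_total_water(sim$soil)
  water <- annual_max_water(total)
  water <- backfill_pre_treatment(water, config$years)
  m <- merge(biomass, water, by = c("plot", "year"))
  rwa <- cbind(m[, c("plot", "year")],
               relative_water_availability(m$max_total_water_mm, m$agb_mean,
                                           m$agb_lo, m$agb_hi))
  res$water <- water
  res$rwa <- rwa

  annual <- merge(merge(biomass[, c("plot", "year", "agb_mean")],
                        delta[, c("plot", "year", "delta_biomass")],
                        by = c("plot", "year")),
                  rwa[, c("plot", "year", "rwa_mean")],
                  by = c("plot", "year"))
  phases <- phase_summary(annual, changepoint_year)
  res$phases <- phases

  ph <- function(pl, phx, var) {
    v <- phases$mean[phases$plot == pl & phases$phase == phx &
                       phases$variable == var]
    if (length(v) == 1) v else NA_real_
  }
  tfe_years <- biomass$year[biomass$plot == "TFE"]
  b0 <- biomass$agb_mean[biomass$plot == "TFE" &
                           biomass$year == min(tfe_years)]
  # last census year before the changepoint (gap years may shift it)
  trans_end <- max(tfe_years[tfe_years < changepoint_year])
  b_end_trans <- biomass$agb_mean[biomass$plot == "TFE" &
                                    biomass$year == trans_end]
  report$tfe_initial_biomass <- b0
  report$tfe_biomass_loss_transition <- b0 - b_end_trans
  report$tfe_pct_biomass_loss <- percent_biomass_change(b0, b0 - b_end_trans)
  report$tfe_stabilization_mean_biomass <- ph("TFE", "stabilization",
                                              "agb_mean")
  report$rwa_tfe_transition <- ph("TFE", "transition", "rwa_mean")
  report$rwa_control_transition <- ph("control", "transition", "rwa_mean")
  report$rwa_tfe_stabilization <- ph("TFE", "stabilization", "rwa_mean")
  report$rwa_control_stabilization <- ph("control", "stabilization",
                                         "rwa_mean")
  report$delta_tfe_transition <- ph("TFE", "transition", "delta_biomass")
  report$delta_tfe_stabilization <- ph("TFE", "stabilization",
                                       "delta_biomass")
  report$delta_control_transition <- ph("control", "transition",
                                        "delta_biomass")
  report$delta_control_stabilization <- ph("control", "stabilization",
                                           "delta_biomass")

  # hydraulics -> daily metrics -> plot comparisons
  res$hydraulic_tests <- NULL
  if ("stats" %in% stages) {
    need_stage("hydraulics", stages, "stats")
    hy <- sim$hydraulics
    meta <- hy$trees
    daily <- lapply(split(hy$sapflow,
                          hy$sapflow$tree_id)[unique(hy$sapflow$tree_id)],
                    function(s) {
      bc <- baseline_correct(s)
      d <- daily_aggregate(bc$series)
      reduction_from_annual_max(d)
    })
    sap_daily <- do.call(rbind, Map(function(d, id) {
      d$tree_id <- id
      d
    }, daily, names(daily)))
    sap_daily <- merge(sap_daily,
                       meta[, c("tree_id", "plot", "genus", "initial_dbh")],
                       by = "tree_id")
    names(sap_daily)[names(sap_daily) == "initial_dbh"] <- "diameter"
    sap_daily <- sap_daily[!is.na(sap_daily$q90) & sap_daily$q90 > 0, ]
    tests <- list()
    tests$sapflow_q90 <- compare_plots(
      sap_daily, comparison_spec("q90", random_structure = "individual_in_genus"))
    red <- sap_daily[sap_daily$reduction_pct >= 0, ]
    tests$sapflow_reduction <- compare_plots(
      red, comparison_spec("reduction_pct"))
    stem <- do.call(rbind, lapply(
      split(hy$stem_vwc, hy$stem_vwc$tree_id)[unique(hy$stem_vwc$tree_id)],
      function(s) {
        s$vwc <- temperature_correct(s$vwc_raw, s$temperature)
        d <- max_daily_stem_vwc(s)
        d$tree_id <- s$tree_id[1]
        d
      }))
    stem <- merge(stem, meta[, c("tree_id", "plot", "genus", "initial_dbh")],
                  by = "tree_id")
    names(stem)[names(stem) == "initial_dbh"] <- "diameter"
    tests$stem_vwc_max <- compare_plots(
      stem, comparison_spec("daily_max"))
    wp <- hy$leaf_wp[hy$leaf_wp$time_of_day == "midday", ]
    tests$leaf_wp_midday <- compare_plots(wp, comparison_spec("wp_mpa"))
    res$hydraulic_tests <- tests
    report$plot_p_sapflow_q90 <- tests$sapflow_q90$plot_p
    report$plot_p_leaf_wp_midday <- tests$leaf_wp_midday$plot_p
    report$plot_p_stem_vwc_max <- tests$stem_vwc_max$plot_p
  } else {
    report$plot_p_sapflow_q90 <- NULL
    report$plot_p_leaf_wp_midday <- NULL
    report$plot_p_stem_vwc_max <- NULL
  }

  # basin context
  if ("basin" %in% stages) {
    grid <- make_basin_grid(seed = derive_seed(config$seed, "basin"))
    tfe_b <- report$tfe_stabilization_mean_biomass
    ctl_b <- ph("control", "stabilization", "agb_mean")
    basin <- list(grid_seed = grid$georef$seed)
    for (b in c("moist_forest", "dry_forest", "savanna")) {
      smp <- sample_biome(grid, b, n = basin_n,
                          seed = derive_seed(config$seed, paste0("basin_", b)))
      basin[[b]] <- list(
        sample_mean_agb = mean(smp$agb),
        diff_tfe = mean_difference(tfe_b, smp),
        diff_control = mean_difference(ctl_b, smp),
        ttest_tfe = plot_vs_distribution_ttest(log(smp$agb), tfe_b),
        ttest_control = plot_vs_distribution_ttest(log(smp$agb), ctl_b))
    }
    res$basin <- basin
    report$basin_diff_tfe_moist_forest <- basin$moist_forest$diff_tfe
    report$basin_diff_tfe_dry_forest <- basin$dry_forest$diff_tfe
    report$basin_diff_tfe_savanna <- basin$savanna$diff_tfe
  }
  res$report <- report

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(biomass, file.path(out_dir, "plot_biomass.csv"),
                     row.names = FALSE)
    utils::write.csv(delta, file.path(out_dir, "delta_biomass.csv"),
                     row.names = FALSE)
    utils::write.csv(rwa, file.path(out_dir, "rwa.csv"), row.names = FALSE)
    utils::write.csv(phases, file.path(out_dir, "phase_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}
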