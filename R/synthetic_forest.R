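#' Default genus pool for synthetic stands
#'
#' Ten common terra-firme genera with literature-style wood densities
#' (g cm^-3) and standard errors; the pool mean density is 0.60 g cm^-3.
#' @export
default_genus_pool <- function() {
  data.frame(
    genus = c("Eschweilera", "Licania", "Protium", "Pouteria", "Virola",
              "Tachigali", "Cecropia", "Inga", "Jacaranda", "Ocotea"),
    wood_density = c(0.84, 0.88, 0.58, 0.74, 0.45, 0.52, 0.36, 0.62, 0.39,
                     0.62),
    wood_density_se = c(0.05, 0.06, 0.04, 0.05, 0.04, 0.05, 0.03, 0.05,
                        0.04, 0.05))
}

#' Scenario configuration for the two-plot synthetic experiment
#'
#' Defines the study conditions the generator emulates: a ~1-ha control and
#' throughfall-exclusion (TFE) plot pair, censused stems >= 10 cm DBH drawn
#' from a truncated Weibull, roughly half the rainfall excluded on the TFE,
#' drought mortality biased toward large stems through an explicit size-bias
#' exponent, and a linear temperature artifact on stem water content.
#' Defaults are calibrated so the undisturbed stand carries about
#' 248 MgC ha^-1 and the TFE trajectory loses roughly a third of it before
#' stabilizing (see the methods vignette for the calibration rationale).
#'
#' @param n_trees_per_plot stems per 1-ha plot (default 500).
#' @param dbh_shape,dbh_scale truncated-Weibull DBH parameters.
#' @param dbh_range DBH truncation bounds (cm), census threshold 10 cm.
#' @param genus_pool data.frame `genus`, `wood_density`, `wood_density_se`.
#' @param years simulated calendar years.
#' @param throughfall_exclusion_fraction fraction of rainfall removed on the
#'   TFE plot (default 0.5).
#' @param mortality_size_bias exponent coupling the drought hazard to
#'   `(DBH/30)^bias`.
#' @param mortality_hazard_scale multiplier of the drought hazard.
#' @param background_hazard baseline annual death hazard.
#' @param water_demand_mm_per_mgc stand water demand per unit biomass
#'   (mm MgC^-1); trees are stressed when the annual maximum soil water per
#'   unit biomass falls below this.
#' @param growth_base_cm median annual DBH increment of an unstressed tree.
#' @param growth_lognorm_sd lognormal spread of individual growth.
#' @param release_strength extra growth of subcanopy trees per unit of
#'   fractional biomass lost (competition release).
#' @param census_noise_sd measurement noise on quarterly circumference
#'   increments (cm).
#' @param spike_rate probability a quarterly reading is a spurious spike.
#' @param spike_magnitude spike size in multiples of `census_noise_sd`.
#' @param gap_years census years with no data collection.
#' @param soil_capacity_mm water-holding capacity of the 0-4 m column.
#' @param et_demand_mm_day unstressed daily evapotranspiration draw.
#' @param soil_stress_fraction storage fraction below which uptake declines.
#' @param rain_monthly_mm monthly rainfall climatology (mm), Jan-Dec.
#' @param rain_gamma_shape shape of the daily rainfall gamma distribution.
#' @param temperature_effect_b stem-VWC temperature artifact (per deg C).
#' @param hydraulic_effect_size injected TFE effect on hydraulic variables,
#'   in units of the between-tree standard deviation (0 = homeostasis).
#' @param n_monitored_per_plot trees per plot carrying sap-flow and stem-VWC
#'   sensors (default 21).
#' @param sapflow_dry_dip named dry-season transpiration dips (fractions)
#'   for control and TFE.
#' @param seed root RNG seed; every stream derives its own child seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_trees_per_plot = 500,
                            dbh_shape = 0.6, dbh_scale = 1.06,
                            dbh_range = c(10, 160),
                            genus_pool = default_genus_pool(),
                            years = 2002:2023,
                            throughfall_exclusion_fraction = 0.5,
                            mortality_size_bias = 1.8,
                            mortality_hazard_scale = 0.45,
                            background_hazard = 0.008,
                            water_demand_mm_per_mgc = 4.2,
                            growth_base_cm = 0.13,
                            growth_lognorm_sd = 0.4,
                            release_strength = 0.5,
                            census_noise_sd = 0.05,
                            spike_rate = 0.01,
                            spike_magnitude = 10,
                            gap_years = c(2008, 2021),
                            soil_capacity_mm = 1040,
                            et_demand_mm_day = 4.5,
                            soil_stress_fraction = 0.65,
                            rain_monthly_mm = c(310, 330, 340, 300, 260, 180,
                                                90, 60, 50, 55, 90, 150),
                            rain_gamma_shape = 0.5,
                            temperature_effect_b = -0.000974,
                            hydraulic_effect_size = 0,
                            n_monitored_per_plot = 21,
                            sapflow_dry_dip = c(control = 0.25, TFE = 0.18),
                            seed = 1) {
  cfg <- as.list(environment())
  if (throughfall_exclusion_fraction < 0 || throughfall_exclusion_fraction > 1)
    stop_config("throughfall_exclusion_fraction must be in [0, 1]")
  if (any(genus_pool$wood_density <= 0))
    stop_config("all wood densities must be positive")
  if (dbh_range[1] < 10)
    stop_config("DBH truncation must respect the 10 cm census threshold")
  if (n_trees_per_plot < 0 || length(years) < 1)
    stop_config("need a non-negative tree count and at least one year")
  structure(cfg, class = "scenario_config")
}

# internal: truncated Weibull draws
rtrunc_weibull <- function(n, shape, scale, lo, hi) {
  u <- stats::runif(n, stats::pweibull(lo, shape, scale),
                    stats::pweibull(hi, shape, scale))
  stats::qweibull(u, shape, scale)
}

#' Generate the two-plot stand
#'
#' Draws a control and a TFE stand with matched genus composition (the same
#' genus sequence is used in both plots, so community composition is paired)
#' and independent DBH draws from the configured truncated Weibull.
#'
#' @param config a [scenario_config()].
#' @return List: `stand` (data.frame of tree records: `tree_id`, `plot`,
#'   `genus`, `species`, `wood_density`, `wood_density_se`,
#'   `bark_thickness`, `initial_dbh`) and `truth` (stand-level ground truth).
#' @export
generate_stand <- function(config) {
  if (!inherits(config, "scenario_config")) stop_config("invalid config")
  n <- config$n_trees_per_plot
  if (n == 0)
    return(list(stand = data.frame(tree_id = character(), plot = character(),
                                   genus = character(), species = character(),
                                   wood_density = numeric(),
                                   wood_density_se = numeric(),
                                   bark_thickness = numeric(),
                                   initial_dbh = numeric()),
                truth = list()))
  set.seed(derive_seed(config$seed, "stand"))
  pool <- config$genus_pool
  gi <- sample(nrow(pool), n, replace = TRUE)
  stands <- lapply(c("control", "TFE"), function(pl) {
    dbh <- rtrunc_weibull(n, config$dbh_shape, config$dbh_scale,
                          config$dbh_range[1], config$dbh_range[2])
    data.frame(
      tree_id = sprintf("%s%03d", ifelse(pl == "TFE", "T", "C"), seq_len(n)),
      plot = pl,
      genus = pool$genus[gi],
      species = paste0(pool$genus[gi], "_sp", 1 + seq_len(n) %% 3),
      wood_density = pool$wood_density[gi],
      wood_density_se = pool$wood_density_se[gi],
      bark_thickness = round(0.3 + 0.015 * dbh, 3),
      initial_dbh = dbh)
  })
  stand <- do.call(rbind, stands)
  list(stand = stand, truth = list(genus_index = gi))
}

#' Simulate hourly soil moisture for both plots
#'
#' A daily water-balance bucket over the 0-4 m column drives the series:
#' stochastic daily rainfall (gamma-distributed, seasonal climatology) enters
#' the column (scaled by 1 - exclusion fraction on the TFE), uptake follows
#' the evapotranspiration demand with a linear reduction below the stress
#' storage fraction, and input exceeding capacity drains. Storage is
#' disaggregated to the five sensor depths with a fixed profile shape
#' normalized so the trapezoid integral of the profile recovers the bucket
#' storage exactly, plus a deterministic diurnal wiggle that cancels in daily
#' means. The per-day budget components are returned so water conservation
#' (input - uptake - drainage = change in storage) is checkable to machine
#' precision.
#'
#' @param config a [scenario_config()].
#' @param resolution `"hourly"` (default) or `"daily"` sensor output.
#' @param constant_theta if non-`NULL`, bypasses the bucket and emits a flat
#'   series at this volumetric water content (no season, no noise).
#' @return List: `soil` (data.frame `plot`, `timestamp`, `depth_m`, `vwc`),
#'   `truth` (per plot: daily budget, annual input/uptake/drainage/storage
#'   and annual maximum storage).
#' @export
simulate_soil_moisture <- function(config, resolution = c("hourly", "daily"),
                                   constant_theta = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(length(config$years) >= 1)
  days <- seq(as.Date(paste0(min(config$years), "-01-01")),
              as.Date(paste0(max(config$years), "-12-31")), by = "day")
  nd <- length(days)
  hours <- if (resolution == "hourly") 0:23 else 12
  plots <- c("control", "TFE")

  if (!is.null(constant_theta)) {
    grid <- expand.grid(depth_m = soil_depths, hour = hours, day = days,
                        plot = plots, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    soil <- data.frame(
      plot = grid$plot,
      timestamp = as.POSIXct(grid$day, tz = "UTC") + grid$hour * 3600,
      depth_m = grid$depth_m, vwc = constant_theta)
    return(list(soil = soil,
                truth = list(constant_theta = constant_theta,
                             total_water_mm = constant_theta * 4000)))
  }

  set.seed(derive_seed(config$seed, "soil"))
  mo <- as.integer(format(days, "%m"))
  mu <- config$rain_monthly_mm[mo] / 30.4
  rain <- stats::rgamma(nd, shape = config$rain_gamma_shape,
                        scale = mu / config$rain_gamma_shape)
  cap <- config$soil_capacity_mm
  truth <- list()
  soil_parts <- list()
  for (pl in plots) {
    excl <- if (pl == "TFE") config$throughfall_exclusion_fraction else 0
    input <- rain * (1 - excl)
    S <- numeric(nd); uptake <- numeric(nd); drain <- numeric(nd)
    s <- cap * 0.8
    s0 <- s
    for (i in seq_len(nd)) {
      up <- config$et_demand_mm_day *
        min(1, s / (config$soil_stress_fraction * cap))
      s1 <- s + input[i] - up
      dr <- max(0, s1 - cap)
      s <- min(max(s1, 0), cap)
      uptake[i] <- up - max(0, -s1)   # uptake curtailed if storage exhausted
      drain[i] <- dr
      S[i] <- s
    }
    yr <- as.integer(format(days, "%Y"))
    truth[[pl]] <- list(
      daily = data.frame(day = days, input = input, uptake = uptake,
                         drainage = drain, storage = S),
      initial_storage = s0,
      annual = data.frame(
        year = sort(unique(yr)),
        input = as.vector(tapply(input, yr, sum)),
        uptake = as.vector(tapply(uptake, yr, sum)),
        drainage = as.vector(tapply(drain, yr, sum)),
        end_storage = as.vector(tapply(S, yr, function(v) v[length(v)])),
        max_storage = as.vector(tapply(S, yr, max))))
    # disaggregate storage to the five sensor depths; trapezoid-exact
    w <- c(0.75, 0.9, 1.0, 1.1, 1.15)
    thick <- diff(soil_depths) * 1000
    norm <- sum((w[-1] + w[-5]) / 2 * thick) / 4000
    w <- w / norm
    theta_day <- outer(S / 4000, w)           # nd x 5
    nh <- length(hours)
    wiggle <- 0.002 * sin(2 * pi * (hours - 6) / 24)
    if (resolution == "daily") wiggle <- 0
    surface_damp <- c(1, 0.6, 0.3, 0.1, 0.05)
    theta <- theta_day[rep(seq_len(nd), each = nh), , drop = FALSE] +
      outer(rep(wiggle, nd), surface_damp)
    ts <- as.POSIXct(rep(days, each = nh), tz = "UTC") +
      rep(hours, nd) * 3600
    soil_parts[[pl]] <- data.frame(
      plot = pl,
      timestamp = rep(ts, times = length(soil_depths)),
      depth_m = rep(soil_depths, each = nd * nh),
      vwc = as.vector(theta))
  }
  list(soil = do.call(rbind, soil_parts), truth = truth)
}

#' Simulate the quarterly dendrometer census with mortality and growth
#'
#' Runs the annual demographic loop: each year the plot's water deficit is
#' the shortfall of the annual maximum soil water against the stand's demand
#' (`water_demand_mm_per_mgc` times live biomass); the death hazard is
#' `1 - exp(-(h0 + k * deficit * (DBH/30)^bias))`, size-biased under water
#' deficit; surviving trees grow by a lognormal DBH increment damped by the
#' deficit and boosted for subcanopy trees by competition release as plot
#' biomass declines. True growth is then observed as quarterly circumference
#' increments with measurement noise and occasional spurious spikes; census
#' gap years are not observed, their growth accumulating into the next
#' reading (dendrometer bands are cumulative).
#'
#' @param stand stand data.frame from [generate_stand()].
#' @param config a [scenario_config()].
#' @param water_by_year data.frame `plot`, `year`, `max_storage` (mm). When
#'   `NULL`, [simulate_soil_moisture()] is run (daily resolution) to get it.
#' @return List: `census` (data.frame `tree_id`, `plot`, `genus`, `date`,
#'   `circumference_increment_cm`), `truth` (death years, true annual DBH
#'   increments, planted spikes, annual deficits).
#' @export
simulate_census <- function(stand, config, water_by_year = NULL) {
  if (nrow(stand) == 0L) stop("stand is empty")
  if (is.null(water_by_year)) {
    sm <- simulate_soil_moisture(config, resolution = "daily")
    water_by_year <- do.call(rbind, lapply(names(sm$truth), function(pl)
      data.frame(plot = pl, year = sm$truth[[pl]]$annual$year,
                 max_storage = sm$truth[[pl]]$annual$max_storage)))
  }
  set.seed(derive_seed(config$seed, "census"))
  years <- config$years
  params <- allometry_params()
  q_months <- c(1, 4, 7, 10)
  season_w <- c(0.35, 0.30, 0.20, 0.15)  # wet-season quarters grow more
  rows <- list()
  truth_inc <- list()
  spikes <- list()
  deficits <- list()
  death_year <- stats::setNames(rep(NA_integer_, nrow(stand)), stand$tree_id)
  for (pl in unique(stand$plot)) {
    st <- stand[stand$plot == pl, ]
    n <- nrow(st)
    dbh <- st$initial_dbh
    alive <- rep(TRUE, n)
    carry <- rep(0, n)  # unrecorded circumference growth (gap years)
    B0 <- sum(kg_to_mgc(agb_kg(dbh, height_from_dbh(dbh, params),
                               st$wood_density, params)))
    for (y in years) {
      B <- sum(kg_to_mgc(agb_kg(dbh[alive],
                                height_from_dbh(dbh[alive], params),
                                st$wood_density[alive], params)))
      W <- water_by_year$max_storage[water_by_year$plot == pl &
                                       water_by_year$year == y]
      deficit <- if (length(W) && B > 0)
        max(0, 1 - W / (config$water_demand_mm_per_mgc * B)) else 0
      deficits[[paste(pl, y)]] <- data.frame(plot = pl, year = y,
                                             deficit = deficit, biomass = B)
      haz <- 1 - exp(-(config$background_hazard +
                         config$mortality_hazard_scale * deficit *
                         (dbh / 30)^config$mortality_size_bias))
      dies <- alive & (stats::runif(n) < haz)
      death_year[st$tree_id[dies]] <- y
      alive[dies] <- FALSE
      release <- ifelse(dbh < 30,
                        1 + config$release_strength * max(0, B0 - B) / B0, 1)
      ddbh <- config$growth_base_cm *
        exp(stats::rnorm(n, 0, config$growth_lognorm_sd)) *
        (1 - deficit) * release
      ddbh[!alive] <- 0
      circ_growth <- pi * ddbh
      truth_inc[[paste(pl, y)]] <- data.frame(
        tree_id = st$tree_id, plot = pl, year = y,
        true_dbh_increment = ddbh, alive = alive)
      if (y %in% config$gap_years) {
        carry <- carry + circ_growth
      } else {
        for (qi in seq_along(q_months)) {
          q_inc <- circ_growth * season_w[qi] +
            (if (qi == 1) carry else 0)
          if (qi == 1) carry <- rep(0, n)
          meas <- q_inc + stats::rnorm(n, 0, config$census_noise_sd)
          is_spike <- stats::runif(n) < config$spike_rate
          sp <- ifelse(is_spike,
                       sample(c(-1, 1), n, replace = TRUE) *
                         config$spike_magnitude * config$census_noise_sd, 0)
          meas <- meas + sp
          date <- as.Date(sprintf("%d-%02d-01", y, q_months[qi]))
          keep <- alive
          if (any(is_spike & keep))
            spikes[[paste(pl, y, qi)]] <- data.frame(
              tree_id = st$tree_id[is_spike & keep], plot = pl, date = date,
              magnitude = sp[is_spike & keep])
          rows[[paste(pl, y, qi)]] <- data.frame(
            tree_id = st$tree_id[keep], plot = pl, genus = st$genus[keep],
            date = date, circumference_increment_cm = meas[keep])
        }
      }
      dbh <- dbh + ddbh
    }
  }
  census <- do.call(rbind, rows)
  row.names(census) <- NULL
  list(census = census,
       truth = list(death_year = death_year,
                    increments = do.call(rbind, truth_inc),
                    spikes = if (length(spikes)) do.call(rbind, spikes)
                             else NULL,
                    deficits = do.call(rbind, deficits)))
}

# internal: pick monitored trees per plot by size strata (8 small, 8 medium,
# 5 big where available; filled from the largest remaining otherwise)
select_monitored <- function(stand, n_per_plot, alive_ids = NULL) {
  # plot order fixed by first appearance, not locale collation, so the
  # RNG-draw-to-tree mapping downstream is reproducible everywhere
  plots <- factor(stand$plot, levels = unique(stand$plot))
  do.call(rbind, lapply(split(stand, plots), function(st) {
    if (!is.null(alive_ids)) st <- st[st$tree_id %in% alive_ids, ]
    st <- st[order(-st$initial_dbh), ]
    small <- st[st$initial_dbh < 30, ]
    medium <- st[st$initial_dbh >= 30 & st$initial_dbh < 60, ]
    big <- st[st$initial_dbh >= 60, ]
    want <- round(n_per_plot * c(small = 8, medium = 8, big = 5) / 21)
    pick <- rbind(utils::head(big, want["big"]),
                  utils::head(medium, want["medium"]),
                  utils::head(small, want["small"]))
    extra <- st[!st$tree_id %in% pick$tree_id, ]
    rbind(pick, utils::head(extra, max(0, n_per_plot - nrow(pick))))
  }))
}

#' Simulate the plant-hydraulic sensor streams and field campaigns
#'
#' Generates, for a monitored subsample of trees, 15-min whole-tree sap flow
#' (baseline offset + slow drift + a diurnal bell scaled by a seasonal
#' dryness forcing), 15-min stem volumetric water content carrying the linear
#' temperature artifact `b`, and the three field campaigns (leaf water
#' potential at predawn and midday; leaf and branch tissue masses). Under the
#' default zero injected treatment effect the TFE and control trees differ
#' only through sampling noise and the configured dry-season transpiration
#' dips - the hydraulic-homeostasis condition.
#'
#' @param stand stand data.frame from [generate_stand()].
#' @param soil optional soil list from [simulate_soil_moisture()] (currently
#'   only used to check campaign-date coverage).
#' @param config a [scenario_config()].
#' @param streams subset of `c("sapflow", "stem_vwc", "campaigns")`.
#' @param year monitoring calendar year (default: last simulated year).
#' @param alive_ids optional ids of trees alive in `year` (from the census
#'   truth); monitoring samples only live trees.
#' @return List of data.frames per stream plus `trees` (monitored metadata
#'   incl. circumference and bark thickness) and `truth` (true temperature
#'   coefficient, injected effect sizes, per-tree amplitudes, offsets,
#'   drifts, dry-season dip depths).
#' @export
simulate_hydraulics <- function(stand, soil = NULL, config,
                                streams = c("sapflow", "stem_vwc",
                                            "campaigns"),
                                year = max(config$years),
                                alive_ids = NULL) {
  set.seed(derive_seed(config$seed, "hydraulics"))
  mon <- select_monitored(stand, config$n_monitored_per_plot, alive_ids)
  mon$circumference <- pi * mon$initial_dbh
  nt <- nrow(mon)
  eff <- config$hydraulic_effect_size
  is_tfe <- mon$plot == "TFE"
  dip <- config$sapflow_dry_dip[ifelse(is_tfe, "TFE", "control")]
  # sapwood fraction and crown exposure vary between trees: lognormal scatter
  amp <- 1.4 * (mon$initial_dbh / 10)^1.6 * exp(stats::rnorm(nt, 0, 0.3))
  offset <- stats::runif(nt, 0.3, 0.9)
  drift <- stats::runif(nt, -1, 1) * 2e-5   # kg h^-1 per hour
  genus_eff <- stats::setNames(
    stats::rnorm(length(unique(mon$genus)), 0, 0.12), unique(mon$genus))
  tree_eff <- stats::rnorm(nt, 0, 0.10)
  out <- list(trees = mon)
  truth <- list(temperature_effect_b = config$temperature_effect_b,
                injected_effect_size = eff,
                sapflow_dry_dip = config$sapflow_dry_dip,
                amplitude = stats::setNames(amp, mon$tree_id),
                baseline_offset = stats::setNames(offset, mon$tree_id),
                baseline_drift = stats::setNames(drift, mon$tree_id))
  dry_of_doy <- function(doy) 0.5 * (1 + cos(2 * pi * (doy - 288) / 365))
  if (any(c("sapflow", "stem_vwc") %in% streams)) {
    ts <- seq(as.POSIXct(paste0(year, "-01-01"), tz = "UTC"),
              as.POSIXct(paste0(year, "-12-31 23:45"), tz = "UTC"),
              by = "15 min")
    if (!is.null(soil)) {
      rng <- range(as.Date(soil$soil$timestamp))
      if (as.Date(min(ts)) < rng[1] || as.Date(max(ts)) > rng[2])
        stop("soil series does not cover the monitoring year")
    }
    doy <- as.integer(format(ts, "%j"))
    hod <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
    dry <- dry_of_doy(doy)
    bell <- pmax(0, sin(pi * (hod - 6) / 12))
    hours_since <- as.numeric(difftime(ts, ts[1], units = "hours"))
    nT <- length(ts)
    if ("sapflow" %in% streams) {
      sf <- vector("list", nt)
      for (i in seq_len(nt)) {
        supply <- 1 - dip[i] * dry
        scale_i <- amp[i] * exp(if (is_tfe[i]) eff * 0.15 else 0)
        sf[[i]] <- data.frame(
          tree_id = mon$tree_id[i], plot = mon$plot[i], timestamp = ts,
          sap_flow_kg_h = offset[i] + drift[i] * hours_since +
            scale_i * bell * supply +
            stats::rnorm(nT, 0, 0.03 * amp[i]))
      }
      out$sapflow <- do.call(rbind, sf)
    }
    if ("stem_vwc" %in% streams) {
      sv <- vector("list", nt)
      for (i in seq_len(nt)) {
        temp <- 25 + 2 * dry + 4 * cos(2 * pi * (hod - 14) / 24) +
          stats::rnorm(nT, 0, 0.3)
        base_i <- stats::runif(1, 0.38, 0.48)
        true_vwc <- base_i - 0.02 * dry * (1 + (if (is_tfe[i]) eff * 0.5 else 0)) -
          0.006 * bell * (0.5 + 0.5 * dry) + stats::rnorm(nT, 0, 5e-4)
        sv[[i]] <- data.frame(
          tree_id = mon$tree_id[i], plot = mon$plot[i], timestamp = ts,
          vwc_raw = true_vwc + (temp - mean(temp)) *
            config$temperature_effect_b,
          temperature = temp)
      }
      out$stem_vwc <- do.call(rbind, sv)
    }
  }
  if ("campaigns" %in% streams) {
    camp <- data.frame(campaign = c("wet_peak", "dry_onset", "dry_peak"),
                       doy = c(135, 196, 288))
    wp <- list(); leaf <- list(); branch <- list()
    for (ci in seq_len(nrow(camp))) {
      dry_c <- dry_of_doy(camp$doy[ci])
      for (tod in c("predawn", "midday")) {
        nb <- 3; nl <- 2
        base <- -(0.15 + 0.55 * dry_c) -
          (if (tod == "midday") 0.5 + 0.9 * dry_c else 0)
        for (b in seq_len(nb)) {
          m <- base + genus_eff[mon$genus] + tree_eff +
            ifelse(is_tfe, -eff * 0.18, 0) +
            stats::rnorm(nt, 0, 0.06)
          for (l in seq_len(nl)) {
            val <- pmin(m + stats::rnorm(nt, 0, 0.05), -0.01)
            wp[[paste(ci, tod, b, l)]] <- data.frame(
              tree_id = mon$tree_id, plot = mon$plot, genus = mon$genus,
              diameter = mon$initial_dbh, campaign = camp$campaign[ci],
              time_of_day = tod, branch = b, leaf = l, wp_mpa = val)
          }
        }
      }
      # leaf tissue masses (RWC) per campaign, one pooled sample per branch
      rwc_true <- pmin(pmax(0.92 - 0.15 * dry_c +
                              ifelse(is_tfe, -eff * 0.02, 0) +
                              stats::rnorm(nt, 0, 0.03), 0.05), 0.999)
      m_dry <- stats::runif(nt, 0.2, 0.5)
      m_turgid <- m_dry * stats::runif(nt, 2.0, 2.4)
      leaf[[ci]] <- data.frame(
        tree_id = mon$tree_id, plot = mon$plot, genus = mon$genus,
        diameter = mon$initial_dbh, campaign = camp$campaign[ci],
        m_fresh = m_dry + rwc_true * (m_turgid - m_dry),
        m_turgid = m_turgid, m_dry = m_dry)
      if (camp$campaign[ci] == "dry_peak") {
        v_fresh <- stats::runif(nt, 0.8, 1.6)
        vwc_true <- pmax(0.45 - 0.05 * dry_c +
                           ifelse(is_tfe, -eff * 0.03, 0) +
                           stats::rnorm(nt, 0, 0.03), 0.05)
        m_dry_b <- v_fresh * stats::runif(nt, 0.4, 0.6)
        branch[[ci]] <- data.frame(
          tree_id = mon$tree_id, plot = mon$plot, genus = mon$genus,
          diameter = mon$initial_dbh, campaign = camp$campaign[ci],
          m_fresh = m_dry_b + vwc_true * v_fresh, m_dry = m_dry_b,
          v_fresh = v_fresh)
      }
    }
    out$leaf_wp <- do.call(rbind, wp)
    out$leaf_tissue <- do.call(rbind, leaf)
    out$branch_tissue <- do.call(rbind, branch)
    row.names(out$leaf_wp) <- NULL
  }
  out$truth <- truth
  out
}

#' Run the whole synthetic scenario
#'
#' Orchestrates stand generation, the soil-moisture series, the quarterly
#' census (with soil-driven mortality) and the hydraulic monitoring year, and
#' assembles the combined ground truth.
#'
#' @param config a [scenario_config()].
#' @param soil_resolution passed to [simulate_soil_moisture()].
#' @param hydraulics simulate the sensor streams too (default TRUE).
#' @return List: `stand`, `soil`, `census`, `hydraulics`, `truth`.
#' @export
simulate_scenario <- function(config = scenario_config(),
                              soil_resolution = "hourly",
                              hydraulics = TRUE) {
  gs <- generate_stand(config)
  sm <- simulate_soil_moisture(config, resolution = soil_resolution)
  water <- do.call(rbind, lapply(names(sm$truth), function(pl)
    data.frame(plot = pl, year = sm$truth[[pl]]$annual$year,
               max_storage = sm$truth[[pl]]$annual$max_storage)))
  cs <- simulate_census(gs$stand, config, water_by_year = water)
  out <- list(stand = gs$stand, soil = sm$soil, census = cs$census,
              truth = c(gs$truth, list(soil = sm$truth), cs$truth,
                        list(water_by_year = water)))
  if (hydraulics) {
    alive <- names(cs$truth$death_year)[is.na(cs$truth$death_year)]
    hy <- simulate_hydraulics(gs$stand, sm, config, alive_ids = alive)
    out$hydraulics <- hy
    out$truth$hydraulics <- hy$truth
  }
  out
}

#' Write a simulated scenario to plain files
#'
#' One CSV per stream plus a JSON ground-truth sidecar.
#'
#' @param sim output of [simulate_scenario()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    stand = file.path(dir, "stand.csv"),
    census = file.path(dir, "census.csv"),
    soil = file.path(dir, "soil.csv"))
  utils::write.csv(sim$stand, paths["stand"], row.names = FALSE)
  utils::write.csv(sim$census, paths["census"], row.names = FALSE)
  utils::write.csv(sim$soil, paths["soil"], row.names = FALSE)
  if (!is.null(sim$hydraulics)) {
    for (nm in c("sapflow", "stem_vwc", "leaf_wp", "leaf_tissue",
                 "branch_tissue")) {
      if (is.null(sim$hydraulics[[nm]])) next
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(sim$hydraulics[[nm]], p, row.names = FALSE)
      paths[nm] <- p
    }
  }
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- sim$truth
  truth$increments <- NULL  # large; keep the sidecar light
  if (!is.null(truth$death_year))
    truth$death_year <- as.list(truth$death_year)  # keep tree ids as keys
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  paths["ground_truth"] <- truth_path
  invisible(paths)
}
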