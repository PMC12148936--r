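#' Actual water availability from precipitation and evapotranspiration
#'
#' `P - ET` (mm yr^-1), a proxy of water available in the soil assuming
#' negligible surface run-off and deep drainage. May be negative. Vectorized
#' over grids: applied to matrices it operates cell-wise.
#'
#' @param precipitation annual precipitation (mm yr^-1).
#' @param evapotranspiration annual evapotranspiration (mm yr^-1).
#' @return `precipitation - evapotranspiration`, same shape as the inputs.
#' @export
water_availability <- function(precipitation, evapotranspiration) {
  precipitation - evapotranspiration
}

#' Synthetic basin grid fixture
#'
#' Builds aligned biome, biomass, precipitation and evapotranspiration grids
#' emulating basin-scale products. Cells are assigned a biome, then biomass is
#' drawn from a biome-specific lognormal matched to the configured mean and
#' standard deviation (floored at a small positive value); precipitation and
#' evapotranspiration are normal draws per biome. Defaults reproduce the
#' published Amazon-region biome biomass statistics (moist forest
#' 266 +/- 85.15, dry forest 124.96 +/- 106.65, savanna 49.00 +/- 63.96
#' MgC ha^-1).
#'
#' @param nrow,ncol grid dimensions (<= 200 each keeps fixtures small).
#' @param biome_fractions named fractions of cells per biome (must sum to 1).
#' @param agb_mean,agb_sd named per-biome biomass mean and s.d. (MgC ha^-1).
#' @param precip_mean,precip_sd,et_mean,et_sd per-biome climate parameters
#'   (mm yr^-1).
#' @param seed integer seed.
#' @return A `basin_grid` list of matrices: `biome` (character), `agb`,
#'   `precipitation`, `evapotranspiration`, plus `georef` metadata.
#' @export
make_basin_grid <- function(nrow = 200, ncol = 200,
                            biome_fractions = c(moist_forest = 0.4,
                                                dry_forest = 0.3,
                                                savanna = 0.3),
                            agb_mean = c(moist_forest = 266,
                                         dry_forest = 124.96,
                                         savanna = 49.00),
                            agb_sd = c(moist_forest = 85.15,
                                       dry_forest = 106.65,
                                       savanna = 63.96),
                            precip_mean = c(moist_forest = 2300,
                                            dry_forest = 1500,
                                            savanna = 1350),
                            precip_sd = c(moist_forest = 350,
                                          dry_forest = 250,
                                          savanna = 250),
                            et_mean = c(moist_forest = 1350,
                                        dry_forest = 1150,
                                        savanna = 1100),
                            et_sd = c(moist_forest = 120, dry_forest = 130,
                                      savanna = 140),
                            seed = 1) {
  stopifnot(abs(sum(biome_fractions) - 1) < 1e-8)
  set.seed(seed)
  n <- nrow * ncol
  biome <- sample(names(biome_fractions), n, replace = TRUE,
                  prob = biome_fractions)
  agb <- precip <- et <- numeric(n)
  for (b in names(biome_fractions)) {
    i <- biome == b
    # lognormal moment match: mean m, sd s
    m <- agb_mean[[b]]; s <- agb_sd[[b]]
    sigma2 <- log(1 + (s / m)^2)
    agb[i] <- stats::rlnorm(sum(i), log(m) - sigma2 / 2, sqrt(sigma2))
    precip[i] <- stats::rnorm(sum(i), precip_mean[[b]], precip_sd[[b]])
    et[i] <- stats::rnorm(sum(i), et_mean[[b]], et_sd[[b]])
  }
  agb <- pmax(agb, 0.1)
  structure(list(
    biome = matrix(biome, nrow, ncol),
    agb = matrix(agb, nrow, ncol),
    precipitation = matrix(precip, nrow, ncol),
    evapotranspiration = matrix(et, nrow, ncol),
    georef = list(nrow = nrow, ncol = ncol, crs = "synthetic", seed = seed)),
    class = "basin_grid")
}

#' Sample coordinates within one biome of a basin grid
#'
#' Uniform sampling without replacement among the biome's cells, with an
#' explicit version of the protocol's similarity requirement: the sample mean
#' biomass must fall within `tolerance` population standard deviations of the
#' full biome mean, redrawing up to `max_retry` times otherwise.
#'
#' @param grid a [make_basin_grid()] object (or list of aligned matrices).
#' @param biome biome class to sample.
#' @param n number of cells (default 10000).
#' @param seed integer seed.
#' @param tolerance allowed |sample mean - population mean| in units of the
#'   population s.d. (default 0.02).
#' @param max_retry redraw attempts (default 20).
#' @return A `biome_sample` data.frame: `biome`, `agb`, `precipitation`,
#'   `evapotranspiration`, `water_availability`.
#' @export
sample_biome <- function(grid, biome, n = 10000, seed = 1, tolerance = 0.02,
                         max_retry = 20) {
  cells <- which(grid$biome == biome)
  if (length(cells) < n)
    stop("biome '", biome, "' has ", length(cells), " cells; cannot sample ",
         n)
  pop <- grid$agb[cells]
  set.seed(seed)
  for (try in seq_len(max_retry)) {
    idx <- sample(cells, n)
    if (n == length(cells) ||
        abs(mean(grid$agb[idx]) - mean(pop)) <= tolerance * stats::sd(pop))
      break
    if (try == max_retry)
      warning("similarity tolerance not met after ", max_retry, " redraws")
  }
  data.frame(biome = biome, agb = grid$agb[idx],
             precipitation = grid$precipitation[idx],
             evapotranspiration = grid$evapotranspiration[idx],
             water_availability = water_availability(
               grid$precipitation[idx], grid$evapotranspiration[idx]))
}

#' One-sample t-test of a plot against a log-biomass distribution
#'
#' Tests whether a plot's biomass differs from a biome's biomass
#' distribution: a two-sided one-sample t-test of the log-transformed biome
#' sample against `log(plot_biomass)`. The statistic is oriented as
#' `(sample mean - log plot) / (sd / sqrt(n))`, so a plot below the biome
#' mean gives a positive t.
#'
#' @param log_biomass_sample log-transformed biomass sample of the biome.
#' @param plot_biomass plot biomass (MgC ha^-1), positive, untransformed.
#' @return List `t`, `p`, `df`, `n`.
#' @export
plot_vs_distribution_ttest <- function(log_biomass_sample, plot_biomass) {
  if (plot_biomass <= 0) stop_domain("plot biomass must be positive")
  if (length(log_biomass_sample) < 2) stop("sample must have n >= 2")
  if (stats::sd(log_biomass_sample) == 0)
    stop("zero-variance sample: t statistic undefined")
  ht <- stats::t.test(log_biomass_sample, mu = log(plot_biomass))
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n = length(log_biomass_sample))
}

#' Absolute difference between a plot and a biome's mean biomass
#'
#' On the raw (non-log) scale: `|mean(biome sample agb) - plot biomass|`.
#'
#' @param plot_biomass plot biomass (MgC ha^-1).
#' @param biome_sample a [sample_biome()] data.frame (or numeric agb vector).
#' @return Difference in MgC ha^-1.
#' @export
mean_difference <- function(plot_biomass, biome_sample) {
  agb <- if (is.data.frame(biome_sample)) biome_sample$agb else biome_sample
  abs(mean(agb) - plot_biomass)
}
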