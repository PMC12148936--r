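#' Remove per-tree growth-increment outliers
#'
#' Dendrometer readings occasionally record spurious jumps (band slippage,
#' transcription errors). Following the census protocol, any circumference
#' increment further than three standard deviations from that individual
#' tree's mean increment is removed (set to `NA`), where mean and s.d. are
#' computed over the tree's own raw increments. Removed values are reported,
#' not zero-imputed: annual growth is later taken as the sum of the remaining
#' quarters, so imputing zeros would bias DBH downward.
#'
#' @param census data.frame with columns `tree_id`, `date` (Date),
#'   `circumference_increment_cm`. Extra columns are preserved.
#' @param n_sd removal threshold in standard deviations (default 3).
#' @return A list with `census` (increments beyond the threshold set to `NA`)
#'   and `removals` (data.frame `tree_id`, `date`, `value`).
#' @export
filter_growth_outliers <- function(census, n_sd = 3) {
  if (nrow(census) == 0L)
    return(list(census = census, removals = census[0, c("tree_id", "date")]))
  x <- census$circumference_increment_cm
  mu <- ave(x, census$tree_id, FUN = function(v) mean(v, na.rm = TRUE))
  nn <- ave(x, census$tree_id, FUN = function(v) sum(!is.na(v)))
  sd_ <- ave(x, census$tree_id, FUN = function(v) stats::sd(v, na.rm = TRUE))
  if (any(nn < 3))
    warning("trees with < 3 observations passed through unfiltered: ",
            paste(unique(census$tree_id[nn < 3]), collapse = ", "))
  # strict inequality: an all-equal series (sd = 0) removes nothing
  out <- !is.na(x) & nn >= 3 & !is.na(sd_) & abs(x - mu) > n_sd * sd_
  removals <- data.frame(tree_id = census$tree_id[out], date = census$date[out],
                         value = x[out])
  census$circumference_increment_cm[out] <- NA_real_
  list(census = census, removals = removals)
}

#' Annual DBH trajectory from circumference increments
#'
#' DBH in year *y* is the previous year's DBH plus the year's summed
#' circumference growth divided by pi. Missing quarters contribute zero
#' growth and are reflected in a completeness fraction; years with no
#' observations at all (census gap years) carry the DBH forward unchanged.
#'
#' @param census data.frame with `tree_id`, `date`, `circumference_increment_cm`
#'   (outlier-filtered; `NA` increments are ignored).
#' @param initial_dbh named numeric vector of starting DBH (cm) per tree, at
#'   the start of the first census year.
#' @param years integer vector of calendar years to cover (default: the range
#'   observed in `census`).
#' @return Long data.frame: `tree_id`, `year`, `dbh` (cm, end of year),
#'   `annual_growth_cm` (circumference), `completeness` (fraction of the four
#'   quarters observed).
#' @export
dbh_trajectory <- function(census, initial_dbh, years = NULL) {
  stopifnot(!is.null(names(initial_dbh)))
  if (is.null(years)) {
    yr <- as.integer(format(census$date, "%Y"))
    years <- seq(min(yr), max(yr))
  }
  ids <- names(initial_dbh)
  yr <- as.integer(format(census$date, "%Y"))
  keep <- census$tree_id %in% ids & yr %in% years
  cen <- census[keep, ]
  yr <- yr[keep]
  key <- factor(paste(cen$tree_id, yr, sep = "\r"),
                levels = paste(rep(ids, each = length(years)),
                               rep(years, length(ids)), sep = "\r"))
  growth <- tapply(ifelse(is.na(cen$circumference_increment_cm), 0,
                          cen$circumference_increment_cm), key, sum)
  nobs <- tapply(!is.na(cen$circumference_increment_cm), key, sum)
  growth[is.na(growth)] <- 0
  nobs[is.na(nobs)] <- 0
  g <- matrix(growth, nrow = length(ids), ncol = length(years), byrow = TRUE)
  dbh <- initial_dbh[ids] + t(apply(g, 1, cumsum)) / pi
  data.frame(
    tree_id = rep(ids, each = length(years)),
    year = rep(years, length(ids)),
    dbh = as.vector(t(dbh)),
    annual_growth_cm = as.vector(t(g)),
    completeness = as.vector(t(matrix(nobs, nrow = length(ids),
                                      byrow = TRUE))) / 4,
    row.names = NULL
  )
}

#' Canopy class from DBH
#'
#' Trees with DBH strictly greater than 30 cm are classed as top-canopy or
#' emergent; the boundary value 30 cm itself is subcanopy.
#'
#' @param dbh diameter (cm); vectorized.
#' @return Character vector, `"topcanopy_emergent"` or `"subcanopy"`.
#' @export
classify_canopy <- function(dbh) {
  if (any(dbh < 0, na.rm = TRUE)) stop_domain("dbh must be non-negative")
  ifelse(dbh > 30, "topcanopy_emergent", "subcanopy")
}

#' Aggregate tree biomass to a plot-year total
#'
#' Sums per-tree carbon over the trees alive in the given year; the mean wood
#' density and both CI bounds are summed separately, so the plot CI is the sum
#' of the tree-level CIs (the census procedure, not an independent-error
#' propagation). Per-hectare values are raw sums under the default 1-ha plot.
#'
#' @param stand data.frame of tree records (`tree_id`, `plot`, `genus`,
#'   `wood_density`, `wood_density_se`).
#' @param trajectory output of [dbh_trajectory()] restricted to one plot.
#' @param year calendar year to aggregate.
#' @param alive_ids tree ids alive (still in the census) in `year`.
#' @param params an [allometry_params()] object.
#' @param plot_area_ha plot area (default 1).
#' @return One-row data.frame: `year`, `agb_mean`, `agb_lo`, `agb_hi`
#'   (MgC ha^-1), `agb_mean_per_tree` (MgC), `n_trees`, `n_subcanopy`,
#'   `n_topcanopy`.
#' @export
aggregate_plot <- function(stand, trajectory, year, alive_ids = stand$tree_id,
                           params = allometry_params(), plot_area_ha = 1) {
  tr <- trajectory[trajectory$year == year & trajectory$tree_id %in% alive_ids, ]
  st <- stand[match(tr$tree_id, stand$tree_id), ]
  if (nrow(tr) == 0L)
    return(data.frame(year = year, agb_mean = 0, agb_lo = 0, agb_hi = 0,
                      agb_mean_per_tree = NA_real_, n_trees = 0L,
                      n_subcanopy = 0L, n_topcanopy = 0L))
  if (anyNA(st$wood_density))
    stop("missing wood density for tree(s): ",
         paste(tr$tree_id[is.na(st$wood_density)], collapse = ", "))
  ci <- agb_with_ci(tr$dbh, st$wood_density, st$wood_density_se, params)
  cf <- params$carbon_fraction
  cls <- classify_canopy(tr$dbh)
  data.frame(
    year = year,
    agb_mean = kg_to_mgc(sum(ci$agb_mean), cf) / plot_area_ha,
    agb_lo   = kg_to_mgc(sum(ci$agb_lo), cf) / plot_area_ha,
    agb_hi   = kg_to_mgc(sum(ci$agb_hi), cf) / plot_area_ha,
    agb_mean_per_tree = kg_to_mgc(mean(ci$agb_mean), cf),
    n_trees = nrow(tr),
    n_subcanopy = sum(cls == "subcanopy"),
    n_topcanopy = sum(cls == "topcanopy_emergent")
  )
}

#' Annual plot biomass series from a census table
#'
#' Full census chain for one or both plots: outlier filtering, DBH
#' trajectories, annual aggregation over live trees. Dead trees leave the sum
#' from their death year onward (live-biomass accounting, no standing-dead
#' pool). Census gap years (years with no observations anywhere in the plot)
#' yield no row, so downstream annual differences divide by the year gap.
#'
#' @param census data.frame `tree_id`, `plot`, `date`,
#'   `circumference_increment_cm`.
#' @param stand tree records with `tree_id`, `plot`, `wood_density`,
#'   `wood_density_se`, `initial_dbh`, and optionally `death_year`.
#' @param params an [allometry_params()] object.
#' @param filter_outliers apply [filter_growth_outliers()] first (default).
#' @param plot_area_ha plot area in hectares.
#' @return data.frame with one row per plot-year (class
#'   `plot_biomass_series`), plus attributes `removals` (outlier log).
#' @export
plot_biomass_series <- function(census, stand, params = allometry_params(),
                                filter_outliers = TRUE, plot_area_ha = 1) {
  removals <- NULL
  if (filter_outliers) {
    f <- filter_growth_outliers(census)
    census <- f$census
    removals <- f$removals
  }
  out <- list()
  for (pl in unique(stand$plot)) {
    st <- stand[stand$plot == pl, ]
    cen <- census[census$plot == pl, ]
    if (nrow(cen) == 0L) next
    yr_obs <- sort(unique(as.integer(format(cen$date, "%Y"))))
    init <- stats::setNames(st$initial_dbh, st$tree_id)
    traj <- dbh_trajectory(cen, init, years = seq(min(yr_obs), max(yr_obs)))
    rows <- lapply(yr_obs, function(y) {
      alive <- if ("death_year" %in% names(st))
        st$tree_id[is.na(st$death_year) | st$death_year > y] else st$tree_id
      aggregate_plot(st, traj, y, alive_ids = alive, params = params,
                     plot_area_ha = plot_area_ha)
    })
    res <- do.call(rbind, rows)
    res$plot <- pl
    out[[pl]] <- res
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  structure(res[, c("plot", setdiff(names(res), "plot"))],
            removals = removals, class = c("plot_biomass_series", "data.frame"))
}

#' Annual biomass change
#'
#' Difference in plot biomass between consecutive *available* years, divided
#' by the number of years between them, so a single missing census year
#' yields a two-year difference divided by two. The first available year has
#' no defined change.
#'
#' @param series a [plot_biomass_series()] data.frame (or any data.frame with
#'   `plot`, `year`, `agb_mean`).
#' @param column biomass column to difference (default `"agb_mean"`).
#' @return data.frame `plot`, `year`, `delta_biomass` (MgC ha^-1 yr^-1; `NA`
#'   in each plot's first year), `year_gap`.
#' @export
delta_biomass <- function(series, column = "agb_mean") {
  do.call(rbind, lapply(split(series, series$plot), function(s) {
    s <- s[order(s$year), ]
    if (nrow(s) < 2)
      return(data.frame(plot = s$plot, year = s$year,
                        delta_biomass = NA_real_, year_gap = NA_real_))
    gap <- c(NA, diff(s$year))
    data.frame(plot = s$plot, year = s$year,
               delta_biomass = c(NA, diff(s[[column]])) / gap,
               year_gap = gap, row.names = NULL)
  }))
}

#' Percent biomass change relative to an initial stock
#'
#' @param initial initial biomass (MgC ha^-1), must be positive.
#' @param loss biomass lost (MgC ha^-1).
#' @return Percentage, `100 * loss / initial`.
#' @examples
#' percent_biomass_change(248, 85) # ~34%
#' @export
percent_biomass_change <- function(initial, loss) {
  if (any(initial <= 0)) stop_domain("initial biomass must be positive")
  100 * loss / initial
}
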