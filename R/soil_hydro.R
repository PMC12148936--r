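#' Sensor depths of the soil-moisture profile
#'
#' Volumetric water content is monitored at 0, 0.5, 1, 2.5 and 4 m. The five
#' sensors bound four depth segments (0-0.5, 0.5-1, 1-2.5, 2.5-4 m) that tile
#' the 0-4 m column.
#' @export
soil_depths <- c(0, 0.5, 1, 2.5, 4)

#' Integrate a soil-moisture profile to total water (mm)
#'
#' Each depth segment's water content is taken as the mean of its two
#' bounding sensors (trapezoid rule) and multiplied by the segment thickness
#' in mm; segment totals are summed over the 0-4 m column. A uniform profile
#' of theta integrates to `theta * 4000` mm. An alternative "top-sensor"
#' strategy (each segment takes its upper sensor's value) is available for
#' sensitivity analysis.
#'
#' @param vwc numeric matrix (rows = records, columns = depths in the order
#'   of `depths`) or a single profile vector.
#' @param depths sensor depths (m), default [soil_depths].
#' @param method `"trapezoid"` (default) or `"top_sensor"`.
#' @return Total water in the column, mm (one value per row).
#' @examples
#' integrate_profile(rep(0.25, 5)) # 1000 mm
#' @export
integrate_profile <- function(vwc, depths = soil_depths,
                              method = c("trapezoid", "top_sensor")) {
  method <- match.arg(method)
  if (is.null(dim(vwc))) vwc <- matrix(vwc, nrow = 1)
  if (ncol(vwc) != length(depths))
    stop("profile must have one column per depth (",
         paste(depths, collapse = ", "), " m)")
  if (anyNA(vwc)) {
    bad <- which(is.na(vwc), arr.ind = TRUE)
    stop("missing VWC at depth ", depths[bad[1, 2]], " m (record ",
         bad[1, 1], ")")
  }
  thick_mm <- diff(depths) * 1000
  seg <- switch(method,
    trapezoid  = (vwc[, -1, drop = FALSE] + vwc[, -ncol(vwc), drop = FALSE]) / 2,
    top_sensor = vwc[, -ncol(vwc), drop = FALSE])
  as.vector(seg %*% thick_mm)
}

#' Total column water series from a long soil table
#'
#' Reshapes a long (plot, timestamp, depth, vwc) table to one total-water
#' value per plot and timestamp via [integrate_profile()].
#'
#' @param soil data.frame with `plot`, `timestamp`, `depth_m`, `vwc`.
#' @param method passed to [integrate_profile()].
#' @return data.frame `plot`, `timestamp`, `total_water_mm`.
#' @export
soil_total_water <- function(soil, method = "trapezoid") {
  do.call(rbind, lapply(split(soil, soil$plot), function(s) {
    ts <- sort(unique(s$timestamp))
    di <- match(s$depth_m, soil_depths)
    if (anyNA(di)) stop("unexpected sensor depth: ",
                        paste(unique(s$depth_m[is.na(di)]), collapse = ", "))
    m <- matrix(NA_real_, length(ts), length(soil_depths))
    m[cbind(match(s$timestamp, ts), di)] <- s$vwc
    data.frame(plot = s$plot[1], timestamp = ts,
               total_water_mm = integrate_profile(m, method = method),
               row.names = NULL)
  }))
}

#' Annual maximum of daily-mean total soil water
#'
#' Sub-daily totals are first aggregated to daily means (the convention used
#' for all meteorological and soil series except precipitation), then the
#' maximum daily mean within each calendar year is taken.
#'
#' @param total data.frame `plot`, `timestamp`, `total_water_mm` (from
#'   [soil_total_water()]).
#' @return data.frame `plot`, `year`, `max_total_water_mm`.
#' @export
annual_max_water <- function(total) {
  day <- as.Date(total$timestamp)
  key <- paste(total$plot, day, sep = "\r")
  sums <- rowsum(total$total_water_mm, key)   # rownames: sorted unique keys
  cnts <- rowsum(rep(1, nrow(total)), key)
  daily <- sums[, 1] / cnts[, 1]
  ids <- rownames(sums)
  plot_ <- sub("\r.*", "", ids)
  yr <- as.integer(substr(sub(".*\r", "", ids), 1, 4))
  agg <- tapply(daily, paste(plot_, yr, sep = "\r"), max)
  nm <- names(agg)
  data.frame(plot = sub("\r.*", "", nm),
             year = as.integer(sub(".*\r", "", nm)),
             max_total_water_mm = as.vector(agg), row.names = NULL)
}

#' Biomass-relative water availability
#'
#' Annual maximum total soil water in the 0-4 m column (mm) divided by annual
#' plot biomass (MgC ha^-1): the stabilization statistic, in mm MgC^-1.
#' Because division by the ordered biomass CI bounds flips the interval (a
#' higher biomass gives lower water per unit biomass), the returned lo/hi are
#' re-sorted so `rwa_lo <= rwa_mean <= rwa_hi`.
#'
#' @param max_water annual maximum water (mm); vectorized.
#' @param biomass annual biomass, MgC ha^-1 (mean estimate).
#' @param biomass_lo,biomass_hi optional CI bounds of biomass.
#' @return data.frame `rwa_mean` and, when bounds are supplied, `rwa_lo`,
#'   `rwa_hi` (mm MgC^-1).
#' @examples
#' relative_water_availability(800, 200) # 4 mm MgC^-1
#' @export
relative_water_availability <- function(max_water, biomass,
                                        biomass_lo = NULL, biomass_hi = NULL) {
  if (any(biomass <= 0, na.rm = TRUE)) stop_domain("biomass must be positive")
  out <- data.frame(rwa_mean = max_water / biomass)
  if (!is.null(biomass_lo) && !is.null(biomass_hi)) {
    if (any(biomass_lo <= 0, na.rm = TRUE))
      stop_domain("biomass CI bounds must be positive")
    a <- max_water / biomass_lo
    b <- max_water / biomass_hi
    out$rwa_lo <- pmin(a, b)
    out$rwa_hi <- pmax(a, b)
  }
  out
}

#' Backfill pre-sensor years with the control-plot mean
#'
#' Soil series start after the experiment did; the pre-treatment value is
#' assumed equal to the whole-period control mean. Every backfilled year is
#' reported in the `imputed` attribute so the imputation is auditable.
#'
#' @param annual data.frame `plot`, `year`, `max_total_water_mm`.
#' @param years integer years the series should cover.
#' @param control name of the control plot (default `"control"`).
#' @return `annual` with missing (plot, year) rows filled by the control-plot
#'   mean over its observed years; attribute `imputed` lists added rows.
#' @export
backfill_pre_treatment <- function(annual, years, control = "control") {
  fill <- mean(annual$max_total_water_mm[annual$plot == control])
  added <- NULL
  for (pl in unique(annual$plot)) {
    missing_years <- setdiff(years, annual$year[annual$plot == pl])
    if (length(missing_years)) {
      add <- data.frame(plot = pl, year = missing_years,
                        max_total_water_mm = fill)
      annual <- rbind(annual, add)
      added <- rbind(added, add)
    }
  }
  annual <- annual[order(annual$plot, annual$year), ]
  row.names(annual) <- NULL
  if (!is.null(added))
    message("backfilled ", nrow(added),
            " plot-year(s) with the control-plot mean (",
            signif(fill, 6), " mm)")
  structure(annual, imputed = added)
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Saturation vapour pressure by the Magnus formula with the Allen (1998)
#' constants, `es = 0.6108 * exp(17.27 T / (T + 237.3))` kPa, times
#' `(1 - RH/100)`.
#'
#' @param temperature air temperature (deg C).
#' @param relative_humidity relative humidity (percent, 0-100).
#' @return VPD (kPa).
#' @examples
#' vpd_from_t_rh(25, 50) # ~1.584 kPa
#' @export
vpd_from_t_rh <- function(temperature, relative_humidity) {
  if (any(relative_humidity < 0 | relative_humidity > 100, na.rm = TRUE))
    stop_domain("relative humidity must be within [0, 100]")
  es <- 0.6108 * exp(17.27 * temperature / (temperature + 237.3))
  es * (1 - relative_humidity / 100)
}
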