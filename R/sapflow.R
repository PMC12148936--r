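#' Quantile check loss
#'
#' `rho_tau(r) = r * (tau - 1(r < 0))`, the objective of quantile regression.
#'
#' @param r residuals.
#' @param tau quantile level in (0, 1).
#' @return Summed check loss.
#' @export
check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

#' Fit a single-covariate quantile regression line
#'
#' Minimizes the check loss for `y ~ a + b x` at level `tau`. The optimum of
#' this linear program is attained at a line interpolating two data points,
#' so the fit runs iteratively reweighted least squares to get close, then
#' polishes by exchange over lines through pairs of small-residual points
#' until the exact objective stops improving. Exact on the series lengths
#' used here (verified against full pair enumeration in the test suite).
#'
#' @param x predictor (e.g. hours since series start).
#' @param y response.
#' @param tau quantile level, default 0.1.
#' @param tol convergence tolerance on the check loss.
#' @param n_candidates number of small-residual points considered in each
#'   exchange round.
#' @return List with `intercept`, `slope`, `fitted`, `objective`.
#' @export
fit_quantile_line <- function(x, y, tau = 0.1, tol = 1e-8, n_candidates = 30) {
  stopifnot(length(x) == length(y), length(y) >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (diff(range(y)) == 0)  # constant series: flat line through it, loss 0
    return(list(intercept = y[1], slope = 0, fitted = rep(y[1], n),
                objective = 0))
  # IRLS on the smoothed check function
  beta <- stats::coef(stats::lm(y ~ x))
  eps <- 1e-6 * stats::sd(y)
  for (it in 1:50) {
    r <- y - beta[1] - beta[2] * x
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    beta_new <- stats::coef(stats::lm(y ~ x, weights = w))
    if (max(abs(beta_new - beta)) < 1e-10 * (1 + max(abs(beta)))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  best <- c(beta[1], beta[2])
  best_obj <- check_loss(y - best[1] - best[2] * x, tau)
  # vertex exchange: the optimum passes through two observations
  repeat {
    r <- y - best[1] - best[2] * x
    cand <- order(abs(r))[seq_len(min(n_candidates, n))]
    improved <- FALSE
    pairs <- utils::combn(cand, 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      obj <- check_loss(y - a - b * x, tau)
      if (obj < best_obj - tol) {
        best <- c(a, b); best_obj <- obj; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(intercept = unname(best[1]), slope = unname(best[2]),
       fitted = unname(best[1] + best[2] * x), objective = best_obj)
}

#' Aggregate a sub-hourly series to hourly means
#'
#' @param series data.frame with `timestamp` (POSIXct) and a value column.
#' @param value name of the value column.
#' @return data.frame `timestamp` (hour floor), value column of hourly means.
#' @export
aggregate_to_hourly <- function(series, value = "sap_flow_kg_h") {
  hour <- as.POSIXct(trunc(series$timestamp, "hours"))
  sums <- rowsum(series[[value]], format(hour, "%Y-%m-%d %H"))
  cnts <- rowsum(rep(1, nrow(series)), format(hour, "%Y-%m-%d %H"))
  out <- data.frame(
    timestamp = as.POSIXct(paste0(rownames(sums), ":00:00"), tz = "UTC"),
    v = sums[, 1] / cnts[, 1], row.names = NULL)
  names(out)[2] <- value
  out[order(out$timestamp), ]
}

#' Zero-baseline a sap-flow series by 10% quantile regression
#'
#' Heat-balance sensors carry a non-zero, slowly drifting floor. Following
#' the processing protocol, the series is aggregated to hourly means, the
#' tau = 0.1 quantile line of hourly sap flow against time (hours since the
#' series start) is fitted, and the fitted values are subtracted from the raw
#' values. Corrected values are not clipped at zero unless requested: the
#' correction is a subtraction, nothing more, so about 10% of hourly values
#' fall below zero by construction.
#'
#' @param series data.frame `timestamp`, `sap_flow_kg_h` for one tree, at
#'   15-min or hourly resolution.
#' @param tau quantile level of the baseline (default 0.1).
#' @param clip_zero clip corrected values at zero (default FALSE).
#' @param min_points,min_days minimum hourly points and span required.
#' @return List: `series` (hourly data.frame with `raw`, `baseline`,
#'   `corrected`), `slope` (per hour), `intercept`.
#' @export
baseline_correct <- function(series, tau = 0.1, clip_zero = FALSE,
                             min_points = 100, min_days = 7) {
  hourly <- aggregate_to_hourly(series)
  hours <- as.numeric(difftime(hourly$timestamp, hourly$timestamp[1],
                               units = "hours"))
  if (nrow(hourly) < min_points || diff(range(hours)) < min_days * 24)
    stop("series too short for baseline correction: need >= ", min_points,
         " hourly points spanning >= ", min_days, " days")
  fit <- fit_quantile_line(hours, hourly$sap_flow_kg_h, tau = tau)
  corrected <- hourly$sap_flow_kg_h - fit$fitted
  if (clip_zero) corrected <- pmax(corrected, 0)
  list(series = data.frame(timestamp = hourly$timestamp,
                           raw = hourly$sap_flow_kg_h,
                           baseline = fit$fitted, corrected = corrected),
       slope = fit$slope, intercept = fit$intercept)
}

#' Sap flow per unit sapwood circumference
#'
#' `SF_area = SF_tree / (A - 2 pi B)` with `A` the stem circumference (cm)
#' and `B` the bark thickness (cm).
#'
#' @param sf_tree whole-tree sap flow (kg h^-1).
#' @param circumference stem circumference A (cm).
#' @param bark_thickness bark thickness B (cm).
#' @return Sap flow per circumference (kg h^-1 cm^-1).
#' @examples
#' sf_per_circumference(10, 100, 1)
#' @export
sf_per_circumference <- function(sf_tree, circumference, bark_thickness) {
  if (any(circumference <= 2 * pi * bark_thickness, na.rm = TRUE))
    stop_domain("circumference must exceed 2*pi*bark_thickness")
  sf_tree / (circumference - 2 * pi * bark_thickness)
}

#' Daily sap-flow statistics from a corrected hourly series
#'
#' Per-day 90% quantile (linear-interpolation quantile, R type 7) and sum of
#' hourly sap flow. Days with fewer than `completeness_threshold` of the 24
#' hourly slots are flagged incomplete and their statistics set missing, to
#' prevent partial days biasing the daily quantile.
#'
#' @param hourly data.frame `timestamp`, `corrected` (or the column named in
#'   `value`).
#' @param value value column (default `"corrected"`).
#' @param completeness_threshold minimum fraction of slots (default 0.8).
#' @return data.frame `date`, `q90`, `daily_sum`, `completeness`, `valid`.
#' @export
daily_aggregate <- function(hourly, value = "corrected",
                            completeness_threshold = 0.8) {
  date <- as.Date(hourly$timestamp)
  sp <- split(hourly[[value]], date)
  q90 <- vapply(sp, function(v) stats::quantile(v, 0.9, names = FALSE,
                                                type = 7), numeric(1))
  dsum <- vapply(sp, sum, numeric(1))
  comp <- vapply(sp, length, numeric(1)) / 24
  valid <- comp >= completeness_threshold
  q90[!valid] <- NA_real_
  dsum[!valid] <- NA_real_
  data.frame(date = as.Date(names(sp)), q90 = q90, daily_sum = dsum,
             completeness = comp, valid = valid, row.names = NULL)
}

#' Daily reduction of sap flow from the annual maximum
#'
#' `100 * (1 - q90_day / max_year(q90))` per tree-year: 0% on the annual-max
#' day, approaching 100% as transpiration shuts down. Quantifies the
#' regulation of transpiration relative to capacity.
#'
#' @param daily data.frame from [daily_aggregate()] for one tree-year (or
#'   with a `date` column spanning one year).
#' @param min_days minimum number of valid days required (default 30).
#' @return `daily` with an added `reduction_pct` column.
#' @export
reduction_from_annual_max <- function(daily, min_days = 30) {
  ok <- !is.na(daily$q90)
  if (sum(ok) < min_days)
    stop("need >= ", min_days, " valid days to compute the annual maximum")
  mx <- max(daily$q90[ok])
  if (mx <= 0) stop("annual maximum q90 must be positive")
  daily$reduction_pct <- 100 * (1 - daily$q90 / mx)
  daily
}
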