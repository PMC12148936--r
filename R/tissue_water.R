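#' Leaf relative water content
#'
#' `RWC = (M_fresh - M_dry) / (M_turgid - M_dry)`: the water held in a leaf
#' relative to its fully hydrated maximum. Valid samples satisfy
#' `M_dry <= M_fresh <= M_turgid`; out-of-range samples yield values outside
#' [0, 1] and are flagged with a warning rather than silently accepted.
#'
#' @param m_fresh fresh mass (g).
#' @param m_turgid turgid mass after rehydration (g).
#' @param m_dry oven-dry mass (g).
#' @return RWC as a fraction; vectorized.
#' @examples
#' rwc(1.2, 1.5, 0.5) # 0.7
#' @export
rwc <- function(m_fresh, m_turgid, m_dry) {
  if (any(m_turgid <= m_dry, na.rm = TRUE))
    stop_domain("turgid mass must exceed dry mass")
  out <- (m_fresh - m_dry) / (m_turgid - m_dry)
  if (any(out < 0 | out > 1, na.rm = TRUE))
    warning("RWC outside [0, 1] for ", sum(out < 0 | out > 1, na.rm = TRUE),
            " sample(s); check mass ordering")
  out
}

#' Branch volumetric water content
#'
#' `VWC = (M_fresh - M_dry) / V_fresh` in g cm^-3, from a bark-free twig
#' segment's fresh mass, dry mass and displaced fresh volume.
#'
#' @param m_fresh fresh mass (g).
#' @param m_dry dry mass (g).
#' @param v_fresh fresh volume (cm^3), positive.
#' @return VWC (g cm^-3); vectorized.
#' @examples
#' branch_vwc(2.0, 1.2, 1.6) # 0.5
#' @export
branch_vwc <- function(m_fresh, m_dry, v_fresh) {
  if (any(v_fresh <= 0, na.rm = TRUE))
    stop_domain("fresh volume must be positive")
  (m_fresh - m_dry) / v_fresh
}

#' Temperature-correct stem volumetric water content
#'
#' Frequency-domain reflectometry readings carry a linear temperature
#' artifact. The correction subtracts `T_diff * b` from the measured value,
#' where `T_diff` is the difference between the measured temperature and the
#' reference (the sensor-year mean) and `b` is the temperature effect,
#' -0.000974 per deg C by default. With the negative default `b`, readings
#' taken warmer than the reference are revised upward, exactly as the printed
#' convention dictates.
#'
#' @param vwc_raw measured stem VWC (m^3 m^-3).
#' @param temperature stem temperature (deg C).
#' @param t_ref reference temperature; defaults to `mean(temperature)` (the
#'   series annual mean).
#' @param b temperature effect (per deg C).
#' @return Corrected VWC; vectorized.
#' @examples
#' temperature_correct(0.40, 30, t_ref = 25) # 0.40487
#' @export
temperature_correct <- function(vwc_raw, temperature,
                                t_ref = mean(temperature, na.rm = TRUE),
                                b = -0.000974) {
  vwc_raw - (temperature - t_ref) * b
}

#' Estimate the stem-VWC temperature artifact from data
#'
#' Regresses raw VWC on the temperature deviation, absorbing slow biological
#' variation into per-day intercepts so only the sub-daily covariation with
#' temperature identifies the artifact slope. Used to verify (or re-derive)
#' the published coefficient on data with a known injected artifact.
#'
#' @param vwc_raw measured stem VWC.
#' @param temperature stem temperature (deg C).
#' @param timestamp POSIXct timestamps (used to form per-day intercepts).
#' @return The estimated slope `b` (per deg C).
#' @export
estimate_temperature_effect <- function(vwc_raw, temperature, timestamp) {
  day <- factor(as.Date(timestamp))
  t_diff <- temperature - mean(temperature, na.rm = TRUE)
  fit <- stats::lm(vwc_raw ~ t_diff + day)
  unname(stats::coef(fit)["t_diff"])
}

#' Daily maximum stem VWC and reduction from the annual maximum
#'
#' Daily maximum of the (temperature-corrected) stem VWC, and the percentage
#' reduction of each daily maximum from the annual maximum:
#' `100 * (1 - daily_max / annual_max)`.
#'
#' @param series data.frame `timestamp`, `vwc` (corrected stem VWC) for one
#'   sensor-year.
#' @return data.frame `date`, `daily_max`, `reduction_pct`.
#' @export
max_daily_stem_vwc <- function(series) {
  sp <- split(series$vwc, as.Date(series$timestamp))
  daily_max <- vapply(sp, max, numeric(1), na.rm = TRUE)
  annual_max <- max(daily_max)
  data.frame(date = as.Date(names(sp)), daily_max = daily_max,
             reduction_pct = 100 * (1 - daily_max / annual_max),
             row.names = NULL)
}
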