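#' Site allometry parameters
#'
#' Coefficients of the two-step allometric chain used at the study site: a
#' saturating height-diameter curve,
#' \deqn{H = a (1 - e^{-r\,\mathrm{DBH}^{c}})}{H = a (1 - exp(-r DBH^c))}
#' and a power-law aboveground-biomass model,
#' \deqn{\mathrm{AGB\ (kg)} = k\,(\mathrm{WD} \cdot H \cdot \mathrm{DBH}^2)^{p}.}{AGB = k (WD H DBH^2)^p.}
#' Defaults are the published site coefficients. Note that, taken verbatim
#' with DBH in cm, the height curve yields heights far above real canopy
#' heights (about 137 m at DBH = 30 cm); the chain is nevertheless applied
#' exactly as published, since the biomass model was fitted against these
#' heights. Coefficients are overridable for sensitivity analysis.
#'
#' @param height_asymptote asymptotic height (m).
#' @param height_rate rate coefficient of the height curve.
#' @param height_exponent DBH exponent of the height curve.
#' @param agb_coefficient multiplier of the biomass power law.
#' @param agb_exponent exponent of the biomass power law.
#' @param carbon_fraction fraction of dry biomass that is carbon (0, 1].
#' @param wd_floor smallest wood density (g cm^-3) used when a lower
#'   confidence bound would be non-positive.
#' @param height_cap optional height cap (m); `Inf` disables capping
#'   (default), matching the published chain.
#' @return An object of class `allometry_params`.
#' @export
allometry_params <- function(height_asymptote = 227.35,
                             height_rate = 0.139,
                             height_exponent = 0.5550,
                             agb_coefficient = 0.088,
                             agb_exponent = 0.954,
                             carbon_fraction = 0.5,
                             wd_floor = 0.05,
                             height_cap = Inf) {
  p <- list(height_asymptote = height_asymptote, height_rate = height_rate,
            height_exponent = height_exponent, agb_coefficient = agb_coefficient,
            agb_exponent = agb_exponent, carbon_fraction = carbon_fraction,
            wd_floor = wd_floor, height_cap = height_cap)
  if (any(vapply(p[1:5], function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop_config("all allometry coefficients must be positive numbers")
  if (carbon_fraction <= 0 || carbon_fraction > 1)
    stop_config("carbon_fraction must be in (0, 1]")
  structure(p, class = "allometry_params")
}

#' Tree height from diameter at breast height
#'
#' @param dbh diameter at breast height (cm); vectorized.
#' @param params an [allometry_params()] object.
#' @return Height (m), bounded above by the asymptote and strictly
#'   increasing in `dbh`.
#' @examples
#' height_from_dbh(30)
#' @export
height_from_dbh <- function(dbh, params = allometry_params()) {
  if (any(dbh < 0, na.rm = TRUE)) stop_domain("dbh must be non-negative")
  h <- params$height_asymptote *
    (1 - exp(-params$height_rate * dbh^params$height_exponent))
  pmin(h, params$height_cap)
}

#' Aboveground biomass (kg) from DBH, height and wood density
#'
#' @param dbh diameter at breast height (cm).
#' @param height tree height (m).
#' @param wd wood density (g cm^-3).
#' @param params an [allometry_params()] object.
#' @return Dry aboveground biomass (kg).
#' @examples
#' agb_kg(30, height_from_dbh(30), 0.6)
#' @export
agb_kg <- function(dbh, height, wd, params = allometry_params()) {
  if (any(c(dbh, height, wd) < 0, na.rm = TRUE))
    stop_domain("dbh, height and wd must be non-negative")
  params$agb_coefficient * (wd * height * dbh^2)^params$agb_exponent
}

#' Aboveground biomass with a wood-density confidence interval
#'
#' Propagates wood-density uncertainty through the biomass model by
#' evaluating it at WD and at WD +/- 1.96 s.e. (the normal-approximation 95%
#' bounds). A lower bound that would be non-positive is floored at
#' `params$wd_floor` with a warning.
#'
#' @param dbh diameter at breast height (cm); vectorized.
#' @param wd wood density (g cm^-3).
#' @param wd_se standard error of the wood density (g cm^-3).
#' @param params an [allometry_params()] object.
#' @param z CI multiplier (1.96 for 95%).
#' @return A data.frame with columns `agb_lo`, `agb_mean`, `agb_hi` (kg),
#'   with `agb_lo <= agb_mean <= agb_hi` row-wise.
#' @export
agb_with_ci <- function(dbh, wd, wd_se, params = allometry_params(), z = 1.96) {
  if (any(wd <= 0, na.rm = TRUE)) stop_domain("wood density must be positive")
  if (any(wd_se < 0, na.rm = TRUE)) stop_domain("wood density s.e. must be >= 0")
  h <- height_from_dbh(dbh, params)
  wd_lo <- wd - z * wd_se
  if (any(wd_lo <= 0, na.rm = TRUE)) {
    warning("lower wood-density bound <= 0 for some trees; floored at ",
            params$wd_floor, " g cm^-3")
    wd_lo <- pmax(wd_lo, params$wd_floor)
  }
  data.frame(agb_lo   = agb_kg(dbh, h, wd_lo, params),
             agb_mean = agb_kg(dbh, h, wd, params),
             agb_hi   = agb_kg(dbh, h, wd + z * wd_se, params))
}
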