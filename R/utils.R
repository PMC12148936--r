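#' Derive a deterministic child seed for a named random stream
#'
#' All stochastic components of the scenario generator draw from their own
#' child seed, derived from the root seed and the stream name. Regenerating a
#' single stream (say, the soil series) therefore reproduces it exactly
#' without replaying every other stream.
#'
#' @param root_seed integer root seed.
#' @param stream character stream name, e.g. `"soil"` or `"census"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(root_seed) + h) %% 2147483647)
}

# internal: stop with a consistent domain-error class
stop_domain <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("tfehydro_domain_error", "error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("tfehydro_config_error", "error")))
}

# internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert dry biomass (kg) to carbon (MgC) and back
#'
#' The allometric chain yields dry aboveground biomass in kg; plot totals are
#' reported as carbon. The carbon fraction defaults to 0.5 (see
#' [allometry_params()]).
#'
#' @param kg biomass in kg.
#' @param mgc carbon in MgC.
#' @param carbon_fraction fraction of dry biomass that is carbon.
#' @return Numeric vector in the target unit.
#' @export
kg_to_mgc <- function(kg, carbon_fraction = 0.5) kg * carbon_fraction / 1000

#' @rdname kg_to_mgc
#' @export
mgc_to_kg <- function(mgc, carbon_fraction = 0.5) mgc * 1000 / carbon_fraction
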