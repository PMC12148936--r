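#' Transform rule for a response variable
#'
#' The analysis protocol log-transforms responses to improve residual
#' normality, with two exceptions: variables measuring a *reduction* (in
#' transpiration or stem water content, bounded at 0) use a square-root
#' transform, and water potentials (negative by definition) take the absolute
#' value before the log. The registry is total: every response name maps to
#' exactly one rule.
#'
#' @param response response variable name.
#' @return One of `"log"`, `"sqrt"`, `"abs_then_log"`.
#' @export
transform_for_response <- function(response) {
  if (grepl("reduction", response, ignore.case = TRUE)) return("sqrt")
  if (grepl("(^|_)wp", response, ignore.case = TRUE)) return("abs_then_log")
  "log"
}

#' Apply a named transform to a response vector
#'
#' @param x numeric response.
#' @param transform `"log"`, `"sqrt"`, `"abs_then_log"` or `"none"`.
#' @return Transformed vector.
#' @export
apply_transform <- function(x, transform) {
  switch(transform,
         log = log(x),
         sqrt = sqrt(x),
         abs_then_log = log(abs(x)),
         none = x,
         stop_config(paste("unknown transform:", transform)))
}

#' Specification of a plot-comparison model
#'
#' @param response name of the response column.
#' @param transform transform rule; `NULL` (default) looks it up with
#'   [transform_for_response()].
#' @param fixed_effects subset of `c("plot", "diameter")`.
#' @param random_structure `"individual_in_genus"`, `"genus"` or `"none"`.
#' @param subset optional logical expression (quoted) evaluated in the data,
#'   e.g. a month or campaign filter.
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(response, transform = NULL,
                            fixed_effects = c("plot", "diameter"),
                            random_structure = c("individual_in_genus",
                                                 "genus", "none"),
                            subset = NULL) {
  random_structure <- match.arg(random_structure)
  stopifnot(all(fixed_effects %in% c("plot", "diameter")))
  structure(list(response = response,
                 transform = transform %||% transform_for_response(response),
                 fixed_effects = fixed_effects,
                 random_structure = random_structure,
                 subset = subset),
            class = "comparison_spec")
}

# internal: fixed-effect table with Wald t tests. For mixed fits the
# reference distribution uses a containment-style denominator df (number of
# sampled units minus the fixed-effect rank) supplied by the caller; plain
# linear models default to their residual df.
wald_table <- function(fit, df = NULL) {
  cc <- stats::coef(summary(fit))
  est <- cc[, 1]; se <- cc[, 2]
  tv <- est / se
  if (is.null(df))
    df <- if (inherits(fit, "merMod")) Inf else stats::df.residual(fit)
  data.frame(term = rownames(cc), estimate = est, se = se,
             p = 2 * stats::pt(-abs(tv), df), row.names = NULL)
}

# internal: fit one model variant, falling back on singular fits
fit_variant <- function(data, response_t, fixed, random) {
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fallback <- FALSE
  repeat {
    if (random == "none") {
      fit <- stats::lm(stats::reformulate(rhs, response_t), data = data)
      return(list(fit = fit, random = random, fallback = fallback))
    }
    re <- switch(random,
                 individual_in_genus = "(1 | genus) + (1 | genus:tree_id)",
                 genus = "(1 | genus)")
    form <- stats::as.formula(paste(response_t, "~", rhs, "+", re))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = data, REML = TRUE)))
    if (!lme4::isSingular(fit, tol = 1e-5))
      return(list(fit = fit, random = random, fallback = fallback))
    fallback <- TRUE
    random <- if (random == "individual_in_genus") "genus" else "none"
  }
}

#' Compare plots with a linear mixed model
#'
#' Fits the transformed response against plot (and optionally diameter) as
#' fixed effects with individual nested within genus as random effects, plus
#' reduced variants excluding genus and diameter, and reports whether the
#' full and reduced models reach converging conclusions about the plot
#' effect (same sign, same significance verdict at `alpha`). Fixed-effect
#' p-values are Wald t tests referred to a containment-style denominator df
#' (sampled trees minus the fixed-effect rank): the plot contrast is a
#' between-tree comparison, and a normal reference at a few dozen trees is
#' anti-conservative. A singular random-effects fit falls back to a reduced
#' random structure with a logged warning.
#'
#' @param data data.frame with the response column plus `plot`, and as
#'   needed `diameter`, `genus`, `tree_id`.
#' @param spec a [comparison_spec()].
#' @param alpha significance level for the convergence verdict.
#' @return A `model_result` list: `terms` (Wald table), `plot_estimate`,
#'   `plot_p`, `n_obs`, `transform`, `random_used`, `singular_fallback`,
#'   `reduced` (per-variant plot effects), `conclusions_converge`.
#' @export
compare_plots <- function(data, spec, alpha = 0.05) {
  if (!is.null(spec$subset))
    data <- data[eval(spec$subset, data, parent.frame()), ]
  data <- data[stats::complete.cases(data[, intersect(
    c(spec$response, "plot", spec$fixed_effects), names(data))]), ]
  if (length(unique(data$plot)) < 2)
    stop("plot comparison needs both plots present")
  # stable, locale-independent factor coding with control as the reference
  lv <- sort(unique(as.character(data$plot)), method = "radix")
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))
  data$plot <- factor(data$plot, levels = lv)
  data$.y <- apply_transform(data[[spec$response]], spec$transform)
  fixed <- unique(c("plot", spec$fixed_effects))
  fixed <- fixed[fixed %in% c("plot", "diameter")]
  full <- fit_variant(data, ".y", fixed, spec$random_structure)
  if (full$fallback)
    warning("singular random-effects fit; reduced to '", full$random, "'")
  # containment df: the plot contrast is a between-tree comparison
  units <- if (!is.null(data$tree_id)) data$tree_id else data$genus
  df_unit <- max(2, length(unique(units)) - (1 + length(fixed)))
  tab <- wald_table(full$fit, df = df_unit)
  prow <- grep("^plot", tab$term)[1]
  # reduced variants: drop diameter, drop genus (keep replicate structure)
  reduced <- list()
  if ("diameter" %in% fixed)
    reduced$no_diameter <- fit_variant(data, ".y", "plot",
                                       spec$random_structure)
  if (spec$random_structure != "none")
    reduced$no_genus <- fit_variant(data, ".y", fixed, "none")
  red <- lapply(reduced, function(v) {
    t2 <- wald_table(v$fit, df = df_unit)
    r <- grep("^plot", t2$term)[1]
    list(estimate = t2$estimate[r], p = t2$p[r])
  })
  est <- tab$estimate[prow]; p <- tab$p[prow]
  conv <- all(vapply(red, function(r)
    sign(r$estimate) == sign(est) && (r$p < alpha) == (p < alpha),
    logical(1)))
  structure(list(terms = tab, plot_estimate = est, plot_p = p,
                 n_obs = nrow(data), transform = spec$transform,
                 random_used = full$random,
                 singular_fallback = full$fallback,
                 reduced = red, conclusions_converge = conv,
                 fit = full$fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("Plot comparison (transform:", x$transform, ", random:", x$random_used,
      ")\n")
  cat(sprintf("  plot effect: %.4f (p = %.4g), n = %d\n",
              x$plot_estimate, x$plot_p, x$n_obs))
  if (length(x$reduced))
    cat("  reduced-model conclusions converge:", x$conclusions_converge, "\n")
  invisible(x)
}

#' Variance in a response explained by genus and by diameter
#'
#' Separate single-factor linear models per factor; returns each factor's
#' R-squared. Quantifies how much taxonomic identity and tree size could
#' confound a plot comparison.
#'
#' @param data data.frame with the response and factor columns.
#' @param response response column name (transformed per its registry rule).
#' @param factors columns to assess (default `c("genus", "diameter")`).
#' @param transform transform rule; `NULL` looks it up.
#' @return Named numeric vector of R-squared values.
#' @export
variance_explained <- function(data, response,
                               factors = c("genus", "diameter"),
                               transform = NULL) {
  y <- apply_transform(data[[response]],
                       transform %||% transform_for_response(response))
  vapply(factors, function(f) {
    x <- data[[f]]
    if (length(unique(x)) < 2) return(NA_real_)
    summary(stats::lm(y ~ x))$r.squared
  }, numeric(1))
}

#' Annual biomass as a function of tree density
#'
#' Linear model of annual plot biomass on tree density (total, top-canopy or
#' subcanopy counts), optionally with calendar year as a covariate to absorb
#' temporal autocorrelation; reports whether adding year changes the
#' significance verdict on the density term.
#'
#' @param series [plot_biomass_series()] rows for a single plot.
#' @param density_class `"total"`, `"topcanopy"` or `"subcanopy"`.
#' @param with_year include year as a covariate (default TRUE reports both).
#' @param response biomass column (default `"agb_mean"`, log-transformed).
#' @param min_years minimum years required (default 5).
#' @return List: `slope`, `p`, `slope_with_year`, `p_with_year`,
#'   `significance_robust_to_year`, `n_years`; slope is `NA` (flagged
#'   `degenerate = TRUE`) when density does not vary.
#' @export
density_biomass_model <- function(series, density_class = c("total",
                                  "topcanopy", "subcanopy"),
                                  with_year = TRUE, response = "agb_mean",
                                  min_years = 5) {
  density_class <- match.arg(density_class)
  if (nrow(series) < min_years)
    stop("need >= ", min_years, " years of biomass data")
  dens <- switch(density_class, total = series$n_trees,
                 topcanopy = series$n_topcanopy,
                 subcanopy = series$n_subcanopy)
  y <- log(series[[response]])
  if (length(unique(dens)) < 2)
    return(list(slope = NA_real_, p = NA_real_, slope_with_year = NA_real_,
                p_with_year = NA_real_, significance_robust_to_year = NA,
                degenerate = TRUE, n_years = nrow(series)))
  f1 <- stats::lm(y ~ dens)
  t1 <- wald_table(f1)
  out <- list(slope = t1$estimate[2], p = t1$p[2], degenerate = FALSE,
              n_years = nrow(series))
  if (with_year) {
    f2 <- stats::lm(y ~ dens + series$year)
    t2 <- wald_table(f2)
    out$slope_with_year <- t2$estimate[2]
    out$p_with_year <- t2$p[2]
    out$significance_robust_to_year <- (out$p < 0.05) == (out$p_with_year < 0.05)
  }
  out
}

#' Class mean growth as a function of biomass-relative water availability
#'
#' Linear model of annual mean growth (per canopy class and plot) on the
#' biomass-relative water availability of the same plot-year, optionally with
#' year as a covariate.
#'
#' @param growth data.frame `year`, `mean_growth` (cm yr^-1) for one plot and
#'   canopy class.
#' @param rwa data.frame `year`, `rwa_mean` for the same plot.
#' @param with_year include year as a covariate.
#' @param transform transform for growth (default `"log"`; growth must be
#'   positive then).
#' @return List: `slope`, `p`, and with-year variants; `NA` slope flagged
#'   `degenerate` when rwa does not vary.
#' @export
growth_water_model <- function(growth, rwa, with_year = TRUE,
                               transform = "log") {
  d <- merge(growth, rwa, by = "year")
  if (nrow(d) < 3) stop("need >= 3 paired years")
  y <- apply_transform(d$mean_growth, transform)
  if (length(unique(d$rwa_mean)) < 2)
    return(list(slope = NA_real_, p = NA_real_, degenerate = TRUE,
                n_years = nrow(d)))
  t1 <- wald_table(stats::lm(y ~ d$rwa_mean))
  out <- list(slope = t1$estimate[2], p = t1$p[2], degenerate = FALSE,
              n_years = nrow(d))
  if (with_year) {
    t2 <- wald_table(stats::lm(y ~ d$rwa_mean + d$year))
    out$slope_with_year <- t2$estimate[2]
    out$p_with_year <- t2$p[2]
    out$significance_robust_to_year <- (out$p < 0.05) == (out$p_with_year < 0.05)
  }
  out
}
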