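# Independent oracles used across the suite. Each is deliberately coded as a
# direct, separate path from the package implementation it checks.

# allometric chain, re-derived through logs (independent arithmetic path)
oracle_tree_mgc <- function(dbh, wd, carbon_fraction = 0.5) {
  h <- 227.35 - 227.35 * exp(-0.139 * exp(0.5550 * log(dbh)))
  agb <- exp(log(0.088) + 0.954 * (log(wd) + log(h) + 2 * log(dbh)))
  agb * carbon_fraction / 1000
}

# brute-force LP-vertex oracle for the tau-quantile line: the optimum passes
# through two observations, so enumerate every pair
oracle_quantile_line <- function(x, y, tau) {
  best <- Inf
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    r <- y - a - b * x
    obj <- sum(r * (tau - (r < 0)))
    if (obj < best) best <- obj
  }
  best
}

# closed-form one-sample t statistic
oracle_t <- function(x, mu) (mean(x) - mu) / (stats::sd(x) / sqrt(length(x)))

# linear-interpolation (type 7) quantile, written out explicitly
oracle_q_type7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# small census table builder
make_census <- function(tree_id, dates, increments, plot = "control",
                        genus = "Protium") {
  n <- length(increments)
  data.frame(tree_id = rep_len(tree_id, n), plot = rep_len(plot, n),
             genus = rep_len(genus, n), date = as.Date(dates),
             circumference_increment_cm = increments)
}

# a small, fast scenario configuration for tests that need the generator but
# not the full 22-year study conditions
small_config <- function(seed = 1, years = 2002:2008, ...) {
  scenario_config(n_trees_per_plot = 60, years = years,
                  gap_years = intersect(2005, years),
                  n_monitored_per_plot = 10, seed = seed, ...)
}

# one plot-comparison p-value from a freshly generated campaign dataset;
# effect is the injected TFE shift in between-tree SD units
wp_plot_pvalue <- function(seed, effect = 0) {
  cfg <- small_config(seed = seed, hydraulic_effect_size = effect)
  st <- generate_stand(cfg)
  hy <- simulate_hydraulics(st$stand, NULL, cfg, streams = "campaigns")
  d <- hy$leaf_wp[hy$leaf_wp$time_of_day == "midday" &
                    hy$leaf_wp$campaign == "dry_peak", ]
  d$tree_id <- as.character(d$tree_id)
  suppressWarnings(compare_plots(d, comparison_spec("wp_mpa"))$plot_p)
}
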