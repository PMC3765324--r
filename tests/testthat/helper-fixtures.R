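# Shared fixtures: all built in code, no files.

# a tiny stratified two-PSU-per-stratum design with a binary outcome
make_strat_fixture <- function() {
  df <- data.frame(
    stratum = rep(c("s1", "s2"), each = 8),
    psu = rep(c("a", "b", "c", "d"), each = 4),
    w = c(1, 2, 1, 2, 3, 1, 2, 1, 1, 1, 2, 2, 1, 3, 1, 1),
    y = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0)
  )
  df
}

# small synthetic survey joined to wealth-score quartiles of the true SES rank
make_small_survey <- function(seed = 11, n_provinces = 2, n_ea = 8,
                              b = 0.4, a = 0.4) {
  cfg <- generator_config(n_provinces = n_provinces, n_ea_per_stratum = n_ea,
                          baseline_a = a, ses_gradient_b = b, seed = seed)
  sim <- simulate_survey(cfg)
  w <- sim$women
  qa <- assign_quantile_groups(w$ses_rank + seq_along(w$ses_rank) * 1e-12,
                               weights = w$analysis_weight, k = 4)
  w$grp <- qa$group
  list(women = w, config = cfg, truth = sim$truth,
       design = survey_design(w$analysis_weight, w$stratum_id, w$ea_id))
}

# random grouped-outcome fixtures for property tests
random_grouped <- function() {
  k <- sample(2:8, 1)
  shares <- stats::runif(k, 0.05, 1)
  shares <- shares / sum(shares)
  prev <- stats::runif(k, 0.01, 0.99)
  grouped_outcome(paste0("g", seq_len(k)), prev, shares)
}

# independent trapezoid-area oracle for the concentration index, coded
# directly from cumulative shares (never calls the package's curve helpers)
trapezoid_ci_oracle <- function(shares, prev) {
  p <- shares / sum(shares)
  mu <- sum(p * prev)
  X <- c(0, cumsum(p))
  Y <- c(0, cumsum(p * prev) / mu)
  area <- 0
  for (q in 2:length(X)) {
    area <- area + (X[q] - X[q - 1]) * (Y[q] + Y[q - 1]) / 2
  }
  2 * (0.5 - area)
}
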