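test_that("household counts are forced by the design and output is deterministic", {
  cfg <- generator_config(n_provinces = 2, n_ea_per_stratum = 2,
                          locality_labels = "urban formal", seed = 7)
  hh <- generate_households(cfg)
  expect_equal(nrow(hh), 2 * 2 * 15)
  expect_true(all(hh$design_weight > 0))
  expect_identical(hh, generate_households(cfg))
  w1 <- generate_outcomes(hh, cfg)
  expect_identical(w1, generate_outcomes(hh, cfg))
  expect_true(all(w1$analysis_weight > 0))
  expect_true(all(w1$coverage %in% c(0, 1)))
})

test_that("config invariants are enforced with named errors", {
  expect_error(generator_config(baseline_a = 0.8, ses_gradient_b = 0.4),
               class = "equicover_invalid_config")
  expect_error(generator_config(n_ea_per_stratum = 0),
               class = "equicover_invalid_config")
  expect_error(generator_config(households_per_ea = 2.5),
               class = "equicover_invalid_config")
  # negative gradients are allowed while probabilities stay in [0, 1]
  cfg <- generator_config(baseline_a = 0.6, ses_gradient_b = -0.4)
  expect_s3_class(cfg, "generator_config")
})

test_that("an unattainable asset is owned by almost nobody", {
  items <- stats::setNames(c(0, 12), c("asset_easy", "asset_rare"))
  cfg <- generator_config(n_provinces = 9, n_ea_per_stratum = 19,
                          asset_items = items, seed = 13)
  hh <- generate_households(cfg)  # > 10,000 households
  expect_gt(nrow(hh), 10000)
  expect_lt(mean(hh$asset_rare), 0.01)
})

test_that("Kish selection is uniform within bands", {
  roster <- data.frame(member_id = c("m1", "m2", "m3", "m4", "m5"),
                       age_band = c("20-29", "20-29", "30-39", "30-39", "30-39"))
  # one member per occupied band, deterministic under a seed
  sel <- kish_select(roster, seed = 4)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$age_band, c("20-29", "30-39"))
  expect_identical(sel, kish_select(roster, seed = 4))
  expect_equal(nrow(kish_select(roster[0, ])), 0)
  single <- data.frame(member_id = "m9", age_band = "40-54")
  expect_equal(kish_select(single, seed = 1)$member_id, "m9")
  # frequencies over many seeds: exact binomial/multinomial tolerance
  picks2 <- vapply(1:10000, function(s) kish_select(roster, seed = s)$member_id[1],
                   character(1))
  expect_lt(abs(mean(picks2 == "m1") - 0.5), 0.02)
  picks3 <- vapply(1:10000, function(s) kish_select(roster, seed = s)$member_id[2],
                   character(1))
  freqs <- table(picks3) / 10000
  expect_true(all(abs(freqs - 1 / 3) < 0.02))
})

test_that("raking matches closed forms and a brute-force IPF oracle", {
  # fixed point: targets equal to current shares leave weights unchanged
  w <- c(1, 2, 3, 4)
  sex <- c("f", "f", "m", "m")
  own <- tapply(w, sex, sum) / sum(w)
  w1 <- rake_weights(w, data.frame(sex = sex), list(sex = own))
  expect_equal(as.numeric(w1), w, tolerance = 1e-10)
  # single binary dimension from 25/75 to 50/50: factors 2 and 2/3
  w2 <- rake_weights(rep(1, 4), data.frame(g = c("a", "b", "b", "b")),
                     list(g = c(a = 0.5, b = 0.5)))
  expect_equal(as.numeric(w2), c(2, 2 / 3, 2 / 3, 2 / 3), tolerance = 1e-10)
  # two-dimension raking on a 2x2 table against a from-scratch IPF loop
  df <- data.frame(r = c("x", "x", "y", "y"), c = c("u", "v", "u", "v"))
  w0 <- c(10, 20, 30, 40)
  margins <- list(r = c(x = 0.4, y = 0.6), c = c(u = 0.55, v = 0.45))
  wr <- rake_weights(w0, df, margins)
  oracle <- w0
  for (it in 1:200) {
    cur <- tapply(oracle, df$r, sum) / sum(oracle)
    oracle <- oracle * (margins$r / cur)[df$r]
    cur <- tapply(oracle, df$c, sum) / sum(oracle)
    oracle <- oracle * (margins$c / cur)[df$c]
  }
  oracle <- oracle * sum(w0) / sum(oracle)
  expect_equal(as.numeric(wr), as.numeric(oracle), tolerance = 1e-6)
  for (m in names(margins)) {
    got <- tapply(wr, df[[m]], sum) / sum(wr)
    expect_equal(as.numeric(got), as.numeric(margins[[m]][names(got)]),
                 tolerance = 1e-6)
  }
  expect_true(all(wr > 0))
  expect_equal(sum(wr), sum(w0), tolerance = 1e-8)
  expect_error(rake_weights(rep(1, 3), data.frame(g = c("a", "a", "a")),
                            list(g = c(a = 0.5, b = 0.5))),
               class = "equicover_raking_failure")
})

test_that("closed-form truth obeys the identities of the linear-in-rank model", {
  cfg <- generator_config(baseline_a = 0.4, ses_gradient_b = 0.4)
  tr <- true_equity_values(cfg)
  expect_equal(tr$true_sii, 0.4)
  expect_equal(tr$true_mu, 0.6)
  expect_equal(tr$true_rii * tr$true_mu, tr$true_sii)
  expect_equal(tr$true_c_grouped, 2 * 0.4 * 0.078125 / 0.6)
  # oracle: trapezoid area of the concentration curve of the implied groups
  r <- attr(tr, "group_ranks")
  h <- 0.4 + 0.4 * r
  expect_equal(tr$true_c_grouped, trapezoid_ci_oracle(rep(0.25, 4), h),
               tolerance = 1e-12)
  zero <- true_equity_values(generator_config(ses_gradient_b = 0))
  expect_equal(zero$true_sii, 0)
  expect_equal(zero$true_rii, 0)
  expect_equal(zero$true_c_grouped, 0)
})

test_that("outcome prevalence follows mu = a + b/2 and the null has no gradient", {
  cfg <- generator_config(n_provinces = 4, n_ea_per_stratum = 19,
                          baseline_a = 0.4, ses_gradient_b = 0.4, seed = 23)
  sim <- simulate_survey(cfg)
  w <- sim$women
  mu_hat <- sum(w$analysis_weight * w$coverage) / sum(w$analysis_weight)
  expect_equal(mu_hat, 0.6, tolerance = 0.03)
  # gradient off: concentration index within Monte-Carlo error of zero
  cfg0 <- generator_config(n_provinces = 4, n_ea_per_stratum = 19,
                           baseline_a = 0.4, ses_gradient_b = 0, seed = 29)
  sim0 <- simulate_survey(cfg0)
  w0 <- sim0$women
  qa <- assign_quantile_groups(w0$ses_rank + seq_along(w0$ses_rank) * 1e-12,
                               weights = w0$analysis_weight, k = 4)
  d0 <- survey_design(w0$analysis_weight, w0$stratum_id, w0$ea_id)
  er <- equity_indices(w0$coverage, qa$group, d0, boot = 0)
  expect_lt(abs(er$concentration_index), 0.03)
  expect_lt(abs(er$sii), 0.08)
})

test_that("missingness mask is applied per outcome at the configured rate", {
  cfg <- generator_config(n_provinces = 2, n_ea_per_stratum = 10,
                          outcome_names = c("a1", "a2"),
                          missing_rate = c(0.3, 0), seed = 17)
  sim <- simulate_survey(cfg)
  expect_equal(mean(is.na(sim$women$a1)), 0.3, tolerance = 0.05)
  expect_equal(mean(is.na(sim$women$a2)), 0)
})

test_that("survey CSV round-trips through the pipeline dialect", {
  cfg <- generator_config(n_provinces = 2, n_ea_per_stratum = 3, seed = 19)
  sim <- simulate_survey(cfg)
  dir <- withr::local_tempdir()
  paths <- write_survey(sim, dir)
  expect_true(all(file.exists(paths)))
  hh <- read.csv(file.path(dir, "households.csv"))
  expect_equal(nrow(hh), nrow(sim$households))
  expect_equal(hh$design_weight, sim$households$design_weight, tolerance = 1e-12)
})
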