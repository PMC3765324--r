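test_that("weighted proportion matches hand arithmetic", {
  d <- survey_design(rep(1, 4))
  expect_equal(weighted_proportion(c(1, 1, 0, 0), d)$proportion, 0.5)
  d2 <- survey_design(c(3, 1))
  expect_equal(weighted_proportion(c(1, 0), d2)$proportion, 0.75)
  # invariant to rescaling all weights
  d3 <- survey_design(c(30, 10))
  est2 <- weighted_proportion(c(1, 0), d2)
  est3 <- weighted_proportion(c(1, 0), d3)
  expect_equal(est2$proportion, est3$proportion)
  expect_equal(est2$se, est3$se, tolerance = 1e-12)
  expect_error(weighted_proportion(c(1, 0), d2, domain = c(FALSE, FALSE)),
               class = "equicover_empty_domain")
  expect_error(weighted_proportion(c(NA, NA), d2), class = "equicover_all_missing")
})

test_that("linearised SE equals direct evaluation of the stratified formula", {
  df <- make_strat_fixture()
  d <- survey_design(df$w, df$stratum, df$psu)
  est <- weighted_proportion(df$y, d)
  # direct formula: z_i = w_i (y_i - p) / W; PSU totals centred within strata
  W <- sum(df$w)
  p <- sum(df$w * df$y) / W
  z <- df$w * (df$y - p) / W
  v <- 0
  for (s in unique(df$stratum)) {
    t_psu <- tapply(z[df$stratum == s], df$psu[df$stratum == s], sum)
    nh <- length(t_psu)
    v <- v + nh / (nh - 1) * sum((t_psu - mean(t_psu))^2)
  }
  expect_equal(est$se, sqrt(v), tolerance = 1e-10)
  expect_true(est$ci[1] >= 0 && est$ci[2] <= 1 &&
                est$proportion >= est$ci[1] && est$proportion <= est$ci[2])
})

test_that("linearised SE is close to a jackknife-over-PSUs estimate", {
  fx <- make_small_survey(seed = 31)
  w <- fx$women
  d <- fx$design
  est <- weighted_proportion(w$coverage, d)
  # delete-one-PSU jackknife, stratified (JKn)
  psus <- unique(paste(d$stratum, d$psu, sep = "|"))
  key <- paste(d$stratum, d$psu, sep = "|")
  stratum_of <- tapply(d$stratum, key, function(s) s[1])
  v <- 0
  for (s in unique(d$stratum)) {
    in_s <- names(stratum_of)[stratum_of == s]
    nh <- length(in_s)
    reps <- vapply(in_s, function(drop) {
      wj <- d$weight
      wj[key == drop] <- 0
      wj[d$stratum == s & key != drop] <- wj[d$stratum == s & key != drop] * nh / (nh - 1)
      sum(wj * w$coverage) / sum(wj)
    }, numeric(1))
    v <- v + (nh - 1) / nh * sum((reps - mean(reps))^2)
  }
  expect_lt(abs(sqrt(v) - est$se) / est$se, 0.15)
})

test_that("grouped prevalence reproduces naive group-by arithmetic", {
  fx <- make_small_survey(seed = 41)
  w <- fx$women
  go <- grouped_prevalence(w$coverage, w$grp, fx$design)
  for (i in seq_len(nrow(go))) {
    sel <- w$grp == go$group[i] & !is.na(w$coverage)
    expect_equal(go$prevalence[i],
                 sum(w$analysis_weight[sel] * w$coverage[sel]) /
                   sum(w$analysis_weight[sel]))
    expect_equal(go$n[i], sum(sel))
  }
  expect_equal(sum(go$share), 1, tolerance = 1e-10)
  expect_equal(attr(go, "mu"), sum(go$share * go$prevalence), tolerance = 1e-10)
})

test_that("grouped mean is the share-weighted mean of group prevalences", {
  two <- grouped_outcome(c("a", "b"), c(0.2, 0.4))
  expect_equal(attr(two, "mu"), 0.3)
  g <- grouped_outcome(paste0("Q", 1:4), c(0.45, 0.55, 0.65, 0.75),
                       share = c(0.3, 0.3, 0.2, 0.2))
  expect_equal(attr(g, "mu"), sum(g$share * g$prevalence))
})

test_that("Rao-Scott F reduces to classical Pearson under equal-weight SRS", {
  set.seed(99)
  n <- 160
  y <- rbinom(n, 1, 0.4)
  grp <- sample(letters[1:4], n, replace = TRUE)
  d <- survey_design(rep(1, n))  # one PSU per record, single stratum
  rs <- rao_scott_f(y, grp, d)
  x2 <- suppressWarnings(chisq.test(table(grp, y), correct = FALSE)$statistic)
  expect_equal(rs$F, unname(x2) / 3, tolerance = 1e-8)
  expect_equal(rs$deff, 1, tolerance = 1e-10)
})

test_that("Rao-Scott F is zero for identical prevalences and weight-scale invariant", {
  y <- rep(c(1, 0, 1, 0), 2)
  grp <- rep(c("a", "b"), each = 4)
  d <- survey_design(rep(2, 8))
  rs <- rao_scott_f(y, grp, d)
  expect_equal(rs$F, 0)
  expect_equal(rs$p_value, 1)
  fx <- make_small_survey(seed = 51)
  d1 <- fx$design
  d2 <- survey_design(d1$weight * 2, d1$stratum, d1$psu)
  r1 <- rao_scott_f(fx$women$coverage, fx$women$grp, d1)
  r2 <- rao_scott_f(fx$women$coverage, fx$women$grp, d2)
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  expect_error(rao_scott_f(rep(1, 8), grp, d), class = "equicover_degenerate_table")
})

test_that("response accounting reports one-decimal percentages with exact fractions", {
  led <- response_accounting(data.frame(
    name = c("interviewed", "refused", "pregnant", "zero"),
    numerator = c(10856, 1252, 1113, 0),
    denominator = c(13440, 13440, 9027, 100)))
  expect_equal(led$pct, c(80.8, 9.3, 12.3, 0))
  expect_equal(led$fraction[1], 10856 / 13440)
  expect_error(response_accounting(data.frame(name = "bad", numerator = 5,
                                              denominator = 4)),
               class = "equicover_inconsistent_ledger")
})
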