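test_that("midpoint ranks are the group midpoints of the cumulative distribution", {
  r <- midpoint_ranks(rep(0.25, 4))
  expect_equal(r$rank, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(r$cum_lower, c(0, 0.25, 0.5, 0.75))
  expect_equal(midpoint_ranks(1)$rank, 0.5)
  # unrounded-share arithmetic, not the published rounding
  r2 <- midpoint_ranks(c(0.358, 0.322, 0.16, 0.16))
  expect_equal(r2$rank[1], 0.179)
  expect_equal(r2$rank[2], 0.519)
  expect_error(midpoint_ranks(c(0.5, -0.1, 0.6)), class = "equicover_invalid_shares")
  expect_error(midpoint_ranks(c(0.2, 0.2)), class = "equicover_invalid_shares")
})

test_that("slope index equals the weighted regression slope on rank scores", {
  g <- grouped_outcome(paste0("Q", 1:4), c(10, 20, 30, 40))
  expect_equal(slope_index(g)$sii, 40)  # collinear group means: exact slope
  flat <- grouped_outcome(paste0("Q", 1:4), rep(7, 4))
  expect_equal(slope_index(flat)$sii, 0)
  two <- grouped_outcome(c("lo", "hi"), c(0, 1))
  expect_equal(slope_index(two)$sii, 2)  # (1-0)/(0.75-0.25)
  # unequal shares: cross-check against an explicit normal-equations solve
  g2 <- grouped_outcome(paste0("g", 1:4), c(0.2, 0.35, 0.3, 0.6),
                        share = c(0.4, 0.3, 0.2, 0.1))
  r <- midpoint_ranks(g2$share)$rank
  Xm <- cbind(1, r)
  W <- diag(g2$share)
  beta <- solve(t(Xm) %*% W %*% Xm, t(Xm) %*% W %*% g2$prevalence)
  expect_equal(slope_index(g2)$sii, beta[2], tolerance = 1e-12)
  expect_error(slope_index(g, ranks = data.frame(rank = rep(0.5, 4))),
               class = "equicover_degenerate_regression")
})

test_that("relative index divides the SII by the population mean", {
  expect_equal(relative_index(0, 0.5)$rii, 0)
  expect_equal(relative_index(2, 4)$rii, 0.5)
  expect_error(relative_index(1, 0), class = "equicover_undefined_rii")
  scaled <- relative_index(list(sii = 2, ci = c(1, 3)), 4)
  expect_equal(scaled$ci, c(0.25, 0.75))
})

test_that("concentration curve accumulates outcome against population share", {
  g <- grouped_outcome(paste0("Q", 1:4), c(10, 20, 30, 40))
  curve <- concentration_curve(g)
  expect_equal(curve$cum_pop, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(curve$cum_outcome, c(0, 0.10, 0.30, 0.60, 1))
  flat <- grouped_outcome(paste0("Q", 1:4), rep(0.3, 4))
  cf <- concentration_curve(flat)
  expect_equal(cf$cum_outcome, cf$cum_pop)  # equality: curve on the diagonal
  extreme <- grouped_outcome(paste0("Q", 1:4), c(0, 0, 0, 0.4))
  expect_equal(concentration_curve(extreme)$cum_outcome, c(0, 0, 0, 0, 1))
})

test_that("concentration index matches the trapezoid-area oracle", {
  g <- grouped_outcome(paste0("Q", 1:4), c(10, 20, 30, 40))
  expect_equal(as.numeric(concentration_index(g)), 0.25)
  expect_equal(as.numeric(concentration_index(g)),
               trapezoid_ci_oracle(g$share, g$prevalence), tolerance = 1e-12)
  flat <- grouped_outcome(paste0("Q", 1:4), rep(0.3, 4))
  expect_equal(as.numeric(concentration_index(flat)), 0)
  extreme <- grouped_outcome(paste0("Q", 1:4), c(0, 0, 0, 0.4))
  # grouped C cannot reach 1: four equal groups cap at 0.75
  expect_equal(as.numeric(concentration_index(extreme)), 0.75)
})

test_that("covariance and trapezoid forms agree on random grouped fixtures", {
  set.seed(1203)
  for (i in 1:1000) {
    g <- random_grouped()
    expect_equal(as.numeric(concentration_index(g)),
                 trapezoid_ci_oracle(g$share, g$prevalence), tolerance = 1e-10)
  }
})

test_that("reversing group order flips SII, RII and C; gap negates", {
  set.seed(77)
  for (i in 1:25) {
    g <- random_grouped()
    rev_g <- grouped_outcome(rev(g$group), rev(g$prevalence), rev(g$share))
    expect_equal(slope_index(rev_g)$sii, -slope_index(g)$sii, tolerance = 1e-10)
    expect_equal(as.numeric(concentration_index(rev_g)),
                 -as.numeric(concentration_index(g)), tolerance = 1e-10)
    expect_equal(absolute_gap(rev_g)$gap, -absolute_gap(g)$gap)
  }
})

test_that("SII is invariant to level shifts and equivariant to scaling", {
  set.seed(88)
  for (i in 1:25) {
    g <- random_grouped()
    shift <- grouped_outcome(g$group, g$prevalence + 3, g$share)
    expect_equal(slope_index(shift)$sii, slope_index(g)$sii, tolerance = 1e-10)
    sc <- grouped_outcome(g$group, g$prevalence * 2.5, g$share)
    expect_equal(slope_index(sc)$sii, 2.5 * slope_index(g)$sii, tolerance = 1e-10)
  }
})

test_that("absolute gap is top minus bottom with one-decimal reporting", {
  g <- grouped_outcome(paste0("Q", 1:4), c(98.8, 97.1, 94.5, 93.2))
  expect_equal(absolute_gap(g)$rounded, -5.6)
  eq <- grouped_outcome(c("a", "b"), c(12, 12))
  expect_equal(absolute_gap(eq)$gap, 0)
})

test_that("odds ratio from prevalences follows odds arithmetic", {
  expect_equal(odds_ratio_from_prevalences(0.5, 0.75), 3)
  expect_equal(odds_ratio_from_prevalences(0.3, 0.3), 1)
  expect_error(odds_ratio_from_prevalences(0, 0.5), class = "equicover_undefined_or")
  expect_error(odds_ratio_from_prevalences(0.5, 1), class = "equicover_undefined_or")
})

test_that("record-level equity indices satisfy the RII x mu = SII identity and are deterministic", {
  fx <- make_small_survey(seed = 21)
  er1 <- equity_indices(fx$women$coverage, fx$women$grp, fx$design,
                        boot = 200, seed = 5)
  er2 <- equity_indices(fx$women$coverage, fx$women$grp, fx$design,
                        boot = 200, seed = 5)
  expect_identical(er1, er2)
  expect_equal(er1$rii * er1$mu, er1$sii, tolerance = 1e-8)
  expect_true(er1$concentration_index >= -1 && er1$concentration_index <= 1)
  expect_true(er1$ci$sii[1] <= er1$ci$sii[2])
  # percent scaling multiplies gap/SII by 100, leaves RII and C untouched
  erp <- equity_indices(fx$women$coverage, fx$women$grp, fx$design,
                        boot = 0, percent = TRUE)
  expect_equal(erp$sii, 100 * er1$sii)
  expect_equal(erp$rii, er1$rii)
  expect_equal(erp$concentration_index, er1$concentration_index)
})
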