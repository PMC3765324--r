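#' Midpoint (ridit) rank scores for ordered socio-economic groups
#'
#' Assigns each ordered group the midpoint of its range in the cumulative
#' population distribution: a group holding share \eqn{p_q} with cumulative
#' lower bound \eqn{c_q} receives rank \eqn{r_q = c_q + p_q/2}. Groups must
#' already be ordered from most disadvantaged to most advantaged; ranks then
#' lie strictly inside (0, 1) and increase with position.
#'
#' @param shares Numeric vector of positive population shares, ordered poorest
#'   to richest, summing to 1 (renormalised when within `tol` of 1).
#' @param tol Tolerance on `sum(shares) - 1` before renormalisation refuses.
#' @return A data frame with columns `share`, `cum_lower` and `rank`, one row
#'   per group, of class `"rank_scores"`.
#' @examples
#' midpoint_ranks(c(0.25, 0.25, 0.25, 0.25))$rank  # 0.125 0.375 0.625 0.875
#' @export
midpoint_ranks <- function(shares, tol = 1e-8) {
  assert_that(is.numeric(shares) && length(shares) >= 1L && all(is.finite(shares)),
              "`shares` must be a finite numeric vector", "equicover_invalid_shares")
  assert_that(all(shares > 0),
              "all group shares must be strictly positive", "equicover_invalid_shares")
  s <- sum(shares)
  assert_that(abs(s - 1) <= max(tol, 1e-8) || abs(s - 1) <= 1e-6,
              sprintf("group shares sum to %.8f, not 1", s), "equicover_invalid_shares")
  shares <- shares / s
  cum_lower <- c(0, cumsum(shares)[-length(shares)])
  out <- data.frame(
    share = shares,
    cum_lower = cum_lower,
    rank = cum_lower + shares / 2
  )
  class(out) <- c("rank_scores", class(out))
  out
}

#' Slope index of inequality (SII)
#'
#' The SII is the slope of a least-squares regression of group outcome level
#' on group midpoint rank, weighted by each group's population share. It is
#' interpreted as the absolute change in the outcome when moving from the
#' bottom (rank 0) to the top (rank 1) of the socio-economic distribution,
#' and equals the regression's predicted value at rank 1 minus rank 0.
#'
#' @param grouped A [grouped_outcome()] object (ordered poorest to richest).
#' @param ranks Optional `rank_scores`; defaults to midpoint ranks of the
#'   grouped population shares.
#' @param conf_level Confidence level for the analytic (WLS, t-based) interval.
#' @return List with `sii`, `se` (analytic WLS standard error; `NA` when the
#'   regression has no residual degrees of freedom) and `ci`.
#' @export
slope_index <- function(grouped, ranks = NULL, conf_level = 0.95) {
  stopifnot(inherits(grouped, "grouped_outcome"))
  if (is.null(ranks)) ranks <- midpoint_ranks(grouped$share)
  r <- ranks$rank
  assert_that(length(r) == nrow(grouped), "ranks and groups differ in length",
              "equicover_invalid_shares")
  assert_that(length(unique(r)) >= 2L, "all rank scores are equal: slope undefined",
              "equicover_degenerate_regression")
  h <- grouped$prevalence
  w <- grouped$share / sum(grouped$share)
  rbar <- sum(w * r)
  hbar <- sum(w * h)
  sxx <- sum(w * (r - rbar)^2)
  sii <- sum(w * (r - rbar) * (h - hbar)) / sxx
  k <- length(r)
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (k > 2) {
    fit <- stats::lm(h ~ r, weights = w)
    # collinear group means give a perfect fit (SE 0); that is informative
    # here, not a misspecification
    se <- suppressWarnings(summary(fit)$coefficients["r", "Std. Error"])
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = k - 2)
    ci <- sii + c(-1, 1) * tq * se
  }
  list(sii = sii, se = se, ci = ci, conf_level = conf_level)
}

#' Relative index of inequality (RII)
#'
#' The RII divides the slope index of inequality by the overall population
#' mean of the outcome, giving the bottom-to-top change relative to the
#' average level.
#'
#' @param sii Slope index of inequality (scalar, or the list returned by
#'   [slope_index()]).
#' @param mu Overall population mean of the outcome, on the same scale as the
#'   prevalences from which `sii` was computed; must be positive.
#' @return List with `rii` and, when `sii` carried an interval, `ci` obtained
#'   by scaling it by `1/mu`.
#' @export
relative_index <- function(sii, mu) {
  ci <- NULL
  if (is.list(sii)) {
    ci <- sii$ci
    sii <- sii$sii
  }
  assert_that(is.numeric(mu) && length(mu) == 1L && is.finite(mu) && mu > 0,
              "RII undefined: population mean must be positive", "equicover_undefined_rii")
  out <- list(rii = sii / mu)
  if (!is.null(ci)) out$ci <- ci / mu
  out
}

#' Concentration curve of a grouped outcome
#'
#' Plots the cumulative share of the outcome against the cumulative share of
#' the population, groups ordered poorest to richest. With \eqn{p_q} the
#' population shares and \eqn{h_q} the group prevalences, the curve passes
#' through \eqn{(X_q, Y_q)} with \eqn{X_q = \sum_{j \le q} p_j} and
#' \eqn{Y_q = \sum_{j \le q} p_j h_j / \mu}. Equality puts the curve on the
#' diagonal.
#'
#' @inheritParams slope_index
#' @return Data frame of curve points `cum_pop`, `cum_outcome`, starting at
#'   (0, 0) and ending at (1, 1).
#' @export
concentration_curve <- function(grouped) {
  stopifnot(inherits(grouped, "grouped_outcome"))
  p <- grouped$share / sum(grouped$share)
  h <- grouped$prevalence
  mu <- sum(p * h)
  assert_that(mu > 0, "concentration curve undefined: mean outcome is zero",
              "equicover_undefined_curve")
  data.frame(
    cum_pop = c(0, cumsum(p)),
    cum_outcome = c(0, cumsum(p * h)) / mu
  )
}

#' Concentration index from grouped data
#'
#' Twice the area between the concentration curve and the line of equality,
#' in \[-1, 1\]; positive values indicate the outcome is concentrated among
#' the better-off. Computed in the grouped covariance form
#' \deqn{C = \frac{2}{\mu} \sum_q p_q h_q r_q - 1,}
#' with \eqn{r_q} the midpoint ranks, which is algebraically identical to the
#' trapezoid-rule area under the curve,
#' \eqn{C = 1 - \sum_q (X_q - X_{q-1})(Y_q + Y_{q-1})}; both are evaluated and
#' cross-checked.
#'
#' @inheritParams slope_index
#' @return Scalar concentration index, with the trapezoid evaluation attached
#'   as attribute `"trapezoid"`.
#' @export
concentration_index <- function(grouped) {
  stopifnot(inherits(grouped, "grouped_outcome"))
  p <- grouped$share / sum(grouped$share)
  h <- grouped$prevalence
  mu <- sum(p * h)
  assert_that(mu > 0, "concentration index undefined: mean outcome is zero",
              "equicover_undefined_curve")
  r <- midpoint_ranks(p)$rank
  c_cov <- 2 * sum(p * h * r) / mu - 1
  curve <- concentration_curve(grouped)
  x <- curve$cum_pop
  y <- curve$cum_outcome
  c_trap <- 1 - sum(diff(x) * (y[-1] + y[-length(y)]))
  if (abs(c_cov - c_trap) > 1e-10) {
    abort(sprintf("internal inconsistency: covariance and trapezoid forms differ by %g",
                  c_cov - c_trap), "equicover_internal")
  }
  structure(c_cov, trapezoid = c_trap)
}

#' Absolute gap between the extreme socio-economic groups
#'
#' Difference in outcome level between the most advantaged and the most
#' disadvantaged group (top minus bottom), in the units of the supplied
#' prevalences (percentage points when those are percentages).
#'
#' @inheritParams slope_index
#' @return List with `gap` (unrounded) and `rounded` (one decimal, the
#'   convention used when tabulating percentage-point gaps).
#' @export
absolute_gap <- function(grouped) {
  stopifnot(inherits(grouped, "grouped_outcome"))
  h <- grouped$prevalence
  assert_that(length(h) >= 2L && !is.na(h[1]) && !is.na(h[length(h)]),
              "absolute gap needs both extreme groups", "equicover_missing_group")
  gap <- h[length(h)] - h[1]
  list(gap = gap, rounded = round(gap, 1))
}

#' Odds ratio from two prevalences
#'
#' The odds ratio of a comparison group against a reference group computed
#' directly from their prevalences; for a saturated dummy-coded logistic model
#' this equals the fitted unadjusted odds ratio.
#'
#' @param p_ref,p_cmp Prevalences strictly inside (0, 1); values above 1 are
#'   interpreted as percentages.
#' @return Scalar odds ratio.
#' @examples
#' odds_ratio_from_prevalences(0.5, 0.75)  # 3
#' @export
odds_ratio_from_prevalences <- function(p_ref, p_cmp) {
  p_ref <- as_proportion(p_ref)
  p_cmp <- as_proportion(p_cmp)
  assert_that(is_prob(p_ref) && is_prob(p_cmp) && p_ref > 0 && p_ref < 1 &&
                p_cmp > 0 && p_cmp < 1,
              "odds ratio undefined at boundary prevalences 0 or 1",
              "equicover_undefined_or")
  (p_cmp / (1 - p_cmp)) / (p_ref / (1 - p_ref))
}

#' Equity indices for a binary outcome, with design-based bootstrap intervals
#'
#' Computes the full set of grouped equity statistics for one binary outcome:
#' per-group weighted prevalences, the absolute top-minus-bottom gap, the
#' slope and relative indices of inequality from midpoint rank scores, and
#' the concentration index. Uncertainty is quantified by a nonparametric
#' bootstrap that resamples primary sampling units within strata (group
#' membership held fixed; shares, ranks and the overall mean are recomputed
#' in every replicate), with percentile intervals.
#'
#' @param y Binary outcome vector (0/1, `NA` allowed; complete-case).
#' @param group Ordered factor of socio-economic groups, poorest first.
#' @param design A [survey_design()] aligned with `y`.
#' @param domain Optional logical vector restricting the analysis domain.
#' @param boot Number of bootstrap replicates (0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf_level Confidence level for percentile intervals.
#' @param percent Report prevalences, gap and SII on the percentage scale
#'   (RII and C are scale-free).
#' @return An object of class `"equity_result"`: a list with the grouped
#'   table, `gap`, `sii`, `rii`, `concentration_index`, bootstrap `ci` for
#'   each, the analytic WLS standard error of the SII, and method metadata.
#' @export
equity_indices <- function(y, group, design, domain = NULL, boot = 1000,
                           seed = NULL, conf_level = 0.95, percent = FALSE) {
  stopifnot(inherits(design, "survey_design"))
  if (!is.null(domain)) {
    y <- ifelse(domain & !is.na(domain), y, NA)
  }
  grouped <- grouped_prevalence(y, group, design)
  mu <- attr(grouped, "mu")
  est <- list(
    gap = absolute_gap(grouped)$gap,
    sii = slope_index(grouped),
    c   = as.numeric(concentration_index(grouped))
  )
  est$rii <- relative_index(est$sii$sii, mu)$rii

  cis <- NULL
  n_bad <- 0L
  if (boot > 0) {
    keep <- !is.na(y)
    reps <- with_seed(seed, psu_bootstrap_equity(
      y[keep], group[keep], design$stratum[keep], design$psu[keep],
      design$weight[keep], B = boot
    ))
    ok <- stats::complete.cases(reps)
    n_bad <- sum(!ok)
    reps <- reps[ok, , drop = FALSE]
    alpha <- (1 - conf_level) / 2
    qs <- function(v) unname(stats::quantile(v, c(alpha, 1 - alpha), type = 7))
    cis <- list(gap = qs(reps[, "gap"]), sii = qs(reps[, "sii"]),
                rii = qs(reps[, "rii"]), c = qs(reps[, "c"]))
  }

  scale <- if (percent) 100 else 1
  out <- list(
    outcome = attr(grouped, "outcome"),
    grouped = grouped,
    mu = mu * scale,
    gap = est$gap * scale,
    sii = est$sii$sii * scale,
    sii_se_analytic = est$sii$se * scale,
    rii = est$rii,
    concentration_index = est$c,
    ci = if (!is.null(cis)) {
      list(gap = cis$gap * scale, sii = cis$sii * scale, rii = cis$rii, c = cis$c)
    },
    method = list(ci_method = "percentile bootstrap over PSUs within strata",
                  boot = boot, boot_dropped = n_bad, seed = seed,
                  conf_level = conf_level, percent = percent)
  )
  class(out) <- "equity_result"
  out
}

# Bootstrap engine: resample PSUs with replacement within each stratum and
# recompute (gap, sii, rii, c) from per-PSU group totals. Vectorised via
# multinomial PSU-resampling counts so B replicates cost a handful of small
# matrix products per stratum.
psu_bootstrap_equity <- function(y, group, stratum, psu, w, B) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  key <- interaction(stratum, psu, drop = TRUE)
  # per-PSU totals of w and w*y within each group
  W <- matrix(0, nlevels(key), k)
  WY <- matrix(0, nlevels(key), k)
  gi <- as.integer(group)
  ki <- as.integer(key)
  for (g in seq_len(k)) {
    sel <- gi == g
    if (any(sel)) {
      t1 <- rowsum(w[sel], ki[sel])
      t2 <- rowsum((w * y)[sel], ki[sel])
      idx <- as.integer(rownames(t1))
      W[idx, g] <- t1
      WY[idx, g] <- t2
    }
  }
  psu_stratum <- tapply(as.character(stratum), ki, function(s) s[1])
  strata <- split(seq_len(nlevels(key)), psu_stratum)

  bw <- matrix(0, B, k)
  bwy <- matrix(0, B, k)
  for (idx in strata) {
    nh <- length(idx)
    counts <- stats::rmultinom(B, nh, rep(1 / nh, nh))  # nh x B
    bw <- bw + crossprod(counts, W[idx, , drop = FALSE])
    bwy <- bwy + crossprod(counts, WY[idx, , drop = FALSE])
  }
  h <- bwy / bw
  p <- bw / rowSums(bw)
  cp <- t(apply(p, 1, cumsum))
  r <- cp - p / 2
  mu <- rowSums(p * h)
  rbar <- rowSums(p * r)
  hbar <- mu
  sxx <- rowSums(p * (r - rbar)^2)
  sxy <- rowSums(p * (r - rbar) * (h - hbar))
  sii <- sxy / sxx
  cbind(
    gap = h[, k] - h[, 1],
    sii = sii,
    rii = sii / mu,
    c = 2 * rowSums(p * h * r) / mu - 1
  )
}

#' @export
print.equity_result <- function(x, ...) {
  cat("Equity indices", if (!is.null(x$outcome)) paste0("for '", x$outcome, "'"), "\n")
  g <- as.data.frame(x$grouped)
  if (isTRUE(x$method$percent)) {
    g$prevalence <- round(100 * g$prevalence, 1)
    g$share <- round(g$share, 3)
    names(g)[names(g) == "prevalence"] <- "prevalence_pct"
  }
  print(g, row.names = FALSE)
  fmt <- function(v, ci, d) {
    s <- formatC(v, digits = d, format = "f")
    if (!is.null(ci)) s <- sprintf("%s (%s to %s)", s,
                                   formatC(ci[1], digits = d, format = "f"),
                                   formatC(ci[2], digits = d, format = "f"))
    s
  }
  cat("  mean:", formatC(x$mu, digits = 3, format = "f"), "\n")
  cat("  gap (top - bottom):", fmt(x$gap, x$ci$gap, 1), "\n")
  cat("  SII:", fmt(x$sii, x$ci$sii, 1), "\n")
  cat("  RII:", fmt(x$rii, x$ci$rii, 2), "\n")
  cat("  C:  ", fmt(x$concentration_index, x$ci$c, 4), "\n")
  invisible(x)
}
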