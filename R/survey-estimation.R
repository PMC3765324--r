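#' Complex-survey design descriptor
#'
#' Bundles the stratum identifier, primary sampling unit (PSU) identifier and
#' analysis weight of each record. Every design-based estimator in the package
#' consumes this object. Omitting `psu` treats each record as its own PSU,
#' i.e. variance estimation that ignores clustering (the replication stance
#' appropriate when the number of PSUs approaches the number of respondents);
#' omitting `stratum` pools all records in a single stratum.
#'
#' @param weight Positive analysis weight per record.
#' @param stratum Optional stratum identifier per record.
#' @param psu Optional PSU identifier per record (unique within stratum).
#' @return An object of class `"survey_design"`.
#' @export
survey_design <- function(weight, stratum = NULL, psu = NULL) {
  n <- length(weight)
  assert_that(is.numeric(weight) && all(is.finite(weight)) && all(weight > 0),
              "analysis weights must be positive and finite", "equicover_invalid_design")
  if (is.null(stratum)) stratum <- rep("_all", n)
  if (is.null(psu)) psu <- seq_len(n)
  assert_that(length(stratum) == n && length(psu) == n,
              "stratum/psu must align with weights", "equicover_invalid_design")
  structure(list(weight = weight, stratum = as.character(stratum),
                 psu = as.character(psu), n = n),
            class = "survey_design")
}

design_subset <- function(design, keep) {
  survey_design(design$weight[keep], design$stratum[keep], design$psu[keep])
}

# Taylor-linearised variance of a total of per-record linearised values z:
# sum over strata of n_h/(n_h - 1) * sum over PSUs of (t_hc - t_h-bar)^2,
# with t_hc the PSU totals. Single-PSU strata contribute zero (certainty).
linearised_variance <- function(z, stratum, psu) {
  key <- paste(stratum, psu, sep = "\r")
  t_hc <- rowsum(z, key, reorder = FALSE)
  h_of <- tapply(stratum, key, function(s) s[1])[rownames(t_hc)]
  v <- 0
  single <- FALSE
  for (h in unique(h_of)) {
    t_h <- t_hc[h_of == h]
    nh <- length(t_h)
    if (nh < 2) { single <- TRUE; next }
    v <- v + nh / (nh - 1) * sum((t_h - mean(t_h))^2)
  }
  if (single) warning("stratum with a single PSU contributes no variance", call. = FALSE)
  v
}

# Residual degrees of freedom of a design: number of PSUs minus strata.
design_df <- function(stratum, psu) {
  key <- paste(stratum, psu, sep = "\r")
  length(unique(key)) - length(unique(stratum))
}

#' Design-based weighted proportion with linearised standard error
#'
#' Estimates the weighted prevalence of a binary outcome,
#' \eqn{\hat p = \sum w_i y_i / \sum w_i}, over the non-missing records of an
#' optional analysis domain. The standard error is by Taylor linearisation of
#' the ratio over PSUs within strata; the confidence interval is Wald on the
#' logit scale (so its bounds always lie inside \[0, 1\]), degenerating to the
#' point estimate at prevalences of exactly 0 or 1.
#'
#' @param y Binary outcome vector (0/1/`NA`).
#' @param design A [survey_design()] aligned with `y`.
#' @param domain Optional logical vector restricting the analysis domain.
#' @param conf_level Confidence level.
#' @return Object of class `"prevalence_estimate"`: list with `proportion`,
#'   `se`, `ci`, and unweighted `n`.
#' @export
weighted_proportion <- function(y, design, domain = NULL, conf_level = 0.95) {
  stopifnot(inherits(design, "survey_design"))
  assert_that(length(y) == design$n, "outcome and design differ in length",
              "equicover_invalid_design")
  if (is.null(domain)) domain <- rep(TRUE, design$n)
  assert_that(any(domain), "analysis domain is empty", "equicover_empty_domain")
  keep <- domain & !is.na(y)
  assert_that(any(keep), "outcome entirely missing in domain", "equicover_all_missing")
  yk <- y[keep]
  assert_that(all(yk %in% c(0, 1)), "outcome must be binary 0/1", "equicover_invalid_outcome")
  w <- design$weight[keep]
  W <- sum(w)
  p <- sum(w * yk) / W
  # domain (subpopulation) estimation: out-of-domain records stay in the
  # design with a zero linearised contribution
  z <- numeric(design$n)
  z[keep] <- w * (yk - p) / W
  v <- linearised_variance(z, design$stratum, design$psu)
  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (p <= 0 || p >= 1 || se == 0) {
    c(p, p)
  } else {
    lgt <- stats::qlogis(p)
    se_l <- se / (p * (1 - p))
    stats::plogis(lgt + c(-1, 1) * zq * se_l)
  }
  structure(list(proportion = p, se = se, ci = ci, n = sum(keep),
                 conf_level = conf_level),
            class = "prevalence_estimate")
}

#' Construct a grouped-outcome table directly from summary numbers
#'
#' Container for per-group weighted prevalences, population shares and
#' unweighted counts of one binary outcome, ordered from the most
#' disadvantaged to the most advantaged group. Useful both as the return
#' shape of [grouped_prevalence()] and for entering published grouped
#' percentages directly.
#'
#' @param labels Ordered group labels, poorest first.
#' @param prevalence Per-group outcome level (proportion or percentage, used
#'   as supplied).
#' @param share Per-group weighted population share (defaults to equal).
#' @param n Optional per-group unweighted counts.
#' @param outcome Optional outcome name.
#' @return A data frame of class `"grouped_outcome"` with attribute `mu`,
#'   the share-weighted overall mean.
#' @export
grouped_outcome <- function(labels, prevalence, share = NULL, n = NULL,
                            outcome = NULL) {
  k <- length(labels)
  if (is.null(share)) share <- rep(1 / k, k)
  assert_that(length(prevalence) == k && length(share) == k,
              "labels, prevalence and share must align", "equicover_invalid_shares")
  assert_that(all(share > 0), "group shares must be positive", "equicover_invalid_shares")
  share <- share / sum(share)
  out <- data.frame(group = as.character(labels), prevalence = prevalence,
                    share = share, n = if (is.null(n)) NA_integer_ else n)
  attr(out, "mu") <- sum(share * prevalence)
  attr(out, "outcome") <- outcome
  class(out) <- c("grouped_outcome", class(out))
  out
}

#' Weighted prevalence of an outcome across ordered groups
#'
#' Per-group weighted prevalence, weighted share of the analysed domain and
#' unweighted count for a binary outcome, complete-case within the domain.
#' The overall mean attached to the result is exactly the share-weighted mean
#' of the group prevalences. Groups carrying zero weight after domain and
#' missingness filters are dropped with a warning.
#'
#' @inheritParams weighted_proportion
#' @param group Factor of group membership (order of levels is kept).
#' @param se Also compute per-group linearised standard errors.
#' @return A [grouped_outcome()] with one row per retained group.
#' @export
grouped_prevalence <- function(y, group, design, domain = NULL, se = FALSE) {
  stopifnot(inherits(design, "survey_design"))
  if (is.null(domain)) domain <- rep(TRUE, design$n)
  keep <- domain & !is.na(y) & !is.na(group)
  assert_that(any(keep), "no records retained", "equicover_empty_domain")
  group <- droplevels(factor(group[keep]))
  y <- y[keep]
  w <- design$weight[keep]
  lv <- levels(group)
  wsum <- tapply(w, group, sum)
  empty <- is.na(wsum) | wsum <= 0
  if (any(empty)) {
    warning("dropping groups with zero weight: ", paste(lv[empty], collapse = ", "),
            call. = FALSE)
    lv <- lv[!empty]
  }
  h <- p <- numeric(length(lv))
  n <- integer(length(lv))
  ses <- rep(NA_real_, length(lv))
  for (i in seq_along(lv)) {
    sel <- group == lv[i]
    h[i] <- sum(w[sel] * y[sel]) / sum(w[sel])
    p[i] <- sum(w[sel]) / sum(w)
    n[i] <- sum(sel)
    if (se) {
      est <- weighted_proportion(ifelse(sel, y, NA), design_subset(design, keep))
      ses[i] <- est$se
    }
  }
  out <- grouped_outcome(lv, h, p, n)
  if (se) out$se <- ses
  out
}

#' Rao-Scott corrected association test for a grouped binary outcome
#'
#' Tests independence of a binary outcome and a grouping variable under a
#' complex design. The Pearson chi-square statistic is computed on the
#' design-weighted cell proportions scaled to the unweighted sample size,
#' then divided by the mean generalised design effect of the cell-proportion
#' estimates (first-order Rao-Scott correction) and referred to an F
#' distribution with \eqn{(R-1)(C-1)} numerator degrees of freedom and the
#' design's residual degrees of freedom (PSUs minus strata) in the
#' denominator. Under equal-weight simple random sampling with independent
#' records the correction is exactly 1 and the statistic reduces to the
#' classical Pearson \eqn{X^2/\mathrm{df}}.
#'
#' @inheritParams grouped_prevalence
#' @return List with `F`, `ndf`, `ddf`, `p_value`, the uncorrected `X2` and
#'   the mean design effect `deff`.
#' @export
rao_scott_f <- function(y, group, design, domain = NULL) {
  stopifnot(inherits(design, "survey_design"))
  if (is.null(domain)) domain <- rep(TRUE, design$n)
  keep <- domain & !is.na(y) & !is.na(group)
  y <- y[keep]
  group <- droplevels(factor(group[keep]))
  w <- design$weight[keep]
  stratum <- design$stratum[keep]
  psu <- design$psu[keep]
  n <- length(y)
  R <- nlevels(group)
  assert_that(R >= 2 && length(unique(y)) == 2,
              "degenerate table: need >= 2 groups and both outcome levels",
              "equicover_degenerate_table")
  W <- sum(w)
  # weighted cell and margin proportions
  p_rc <- matrix(0, R, 2)
  for (r in seq_len(R)) {
    sel <- group == levels(group)[r]
    p_rc[r, 2] <- sum(w[sel] * y[sel]) / W
    p_rc[r, 1] <- sum(w[sel] * (1 - y[sel])) / W
  }
  p_r <- rowSums(p_rc)
  p_c <- colSums(p_rc)
  assert_that(all(p_r > 0) && all(p_c > 0), "degenerate table: empty row or column",
              "equicover_degenerate_table")
  expected <- outer(p_r, p_c)
  X2 <- n * sum((p_rc - expected)^2 / expected)

  # cell design effects: linearised variance of each cell proportion over the
  # SRS benchmark p(1-p)/(n-1); cells with no variance are excluded.
  deffs <- c()
  for (r in seq_len(R)) for (cc in 1:2) {
    ind <- as.numeric(group == levels(group)[r] & y == (cc - 1))
    p <- p_rc[r, cc]
    if (p <= 0 || p >= 1) next
    z <- w * (ind - p) / W
    v_des <- linearised_variance(z, stratum, psu)
    v_srs <- p * (1 - p) / (n - 1)
    if (v_srs > 0) deffs <- c(deffs, v_des / v_srs)
  }
  deff <- if (length(deffs)) mean(deffs) else 1
  ndf <- (R - 1) * (2 - 1)
  ddf <- max(design_df(stratum, psu), 1L)
  Fstat <- (X2 / deff) / ndf
  list(F = Fstat, ndf = ndf, ddf = ddf,
       p_value = stats::pf(Fstat, ndf, ddf, lower.tail = FALSE),
       X2 = X2, deff = deff)
}

#' Survey response accounting
#'
#' Turns a ledger of nested fieldwork counts into response rates: each rate is
#' `numerator / denominator`, retained as an unrounded fraction and reported
#' as a percentage rounded to one decimal.
#'
#' @param ledger Data frame with columns `name`, `numerator`, `denominator`.
#' @return The ledger with `fraction` and `pct` (one decimal) appended.
#' @examples
#' response_accounting(data.frame(name = "interviewed",
#'                                numerator = 10856, denominator = 13440))
#' @export
response_accounting <- function(ledger) {
  assert_that(is.data.frame(ledger) &&
                all(c("name", "numerator", "denominator") %in% names(ledger)),
              "ledger needs columns name, numerator, denominator",
              "equicover_inconsistent_ledger")
  assert_that(all(ledger$numerator >= 0) && all(ledger$denominator > 0),
              "counts must be non-negative with positive denominators",
              "equicover_inconsistent_ledger")
  assert_that(all(ledger$numerator <= ledger$denominator),
              "a subset count exceeds its parent", "equicover_inconsistent_ledger")
  ledger$fraction <- ledger$numerator / ledger$denominator
  ledger$pct <- round(100 * ledger$fraction, 1)
  ledger
}
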