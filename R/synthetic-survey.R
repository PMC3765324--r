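#' Configuration for the synthetic household-survey generator
#'
#' Describes a multistage stratified design — strata formed by province x
#' locality, a fixed number of enumerator areas (EAs, the primary sampling
#' units) sampled per stratum, and a fixed take of households per EA — plus a
#' latent living-standards model driving asset ownership and binary maternal
#' outcomes with a configurable socio-economic gradient. Defaults mirror the
#' design of a national South African household survey: 9 provinces x 4
#' locality types, 28 EAs per stratum (1008 EAs), 15 households per EA.
#'
#' The outcome model is linear in the weighted socio-economic rank
#' \eqn{F \in [0, 1]} of the household: \eqn{\Pr(y = 1) = a + b F}. Under this
#' model the true slope index of inequality equals `b` exactly and closed-form
#' values for the other equity indices are available from
#' [true_equity_values()].
#'
#' @param n_provinces Number of provinces.
#' @param n_ea_per_stratum EAs sampled per province-x-locality stratum.
#' @param households_per_ea Households sampled per EA (design constant 15).
#' @param locality_labels Locality types crossing provinces to form strata.
#' @param asset_items Named numeric vector of asset difficulty parameters on
#'   the latent scale: item j is owned with probability
#'   `plogis(latent_ses - difficulty_j)`.
#' @param baseline_a Outcome probability at the bottom of the SES
#'   distribution (rank 0), in \[0, 1\]; recycled over outcomes.
#' @param ses_gradient_b Change in outcome probability from rank 0 to rank 1;
#'   `baseline_a + ses_gradient_b` must stay in \[0, 1\]; recycled.
#' @param outcome_names Names of the binary outcomes to generate.
#' @param missing_rate Per-outcome probability of a missing-completely-at-
#'   random response; recycled.
#' @param weight_dispersion Standard deviation of the multiplicative
#'   log-normal weight jitter (0 = exact inverse-probability weights).
#' @param ea_frame_size Notional EAs per stratum in the sampling frame (first-
#'   stage selection probability = `n_ea_per_stratum / ea_frame_size`).
#' @param hh_frame_size Notional households per EA in the frame (second-stage
#'   selection probability = `households_per_ea / hh_frame_size`).
#' @param seed Integer seed; all generator output is deterministic given the
#'   config including its seed.
#' @return Validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_provinces = 9,
                             n_ea_per_stratum = 28,
                             households_per_ea = 15,
                             locality_labels = c("urban formal", "urban informal",
                                                 "rural informal", "rural formal"),
                             asset_items = stats::setNames(
                               seq(-2, 2, length.out = 8),
                               paste0("asset_", 1:8)),
                             baseline_a = 0.4,
                             ses_gradient_b = 0.4,
                             outcome_names = "coverage",
                             missing_rate = 0,
                             weight_dispersion = 0.2,
                             ea_frame_size = 2400,
                             hh_frame_size = 150,
                             seed = 1L) {
  cfg <- list(n_provinces = n_provinces, n_ea_per_stratum = n_ea_per_stratum,
              households_per_ea = households_per_ea,
              locality_labels = locality_labels, asset_items = asset_items,
              baseline_a = baseline_a, ses_gradient_b = ses_gradient_b,
              outcome_names = outcome_names, missing_rate = missing_rate,
              weight_dispersion = weight_dispersion,
              ea_frame_size = ea_frame_size, hh_frame_size = hh_frame_size,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  for (f in c("n_provinces", "n_ea_per_stratum", "households_per_ea")) {
    assert_that(is_count(cfg[[f]]), sprintf("`%s` must be a positive integer", f),
                "equicover_invalid_config")
  }
  assert_that(length(cfg$locality_labels) >= 1L,
              "`locality_labels` must be non-empty", "equicover_invalid_config")
  assert_that(is.numeric(cfg$asset_items) && length(cfg$asset_items) >= 1L &&
                !is.null(names(cfg$asset_items)),
              "`asset_items` must be a named numeric vector of difficulties",
              "equicover_invalid_config")
  n_out <- length(cfg$outcome_names)
  assert_that(n_out >= 1L, "`outcome_names` must be non-empty",
              "equicover_invalid_config")
  a <- rep_len(cfg$baseline_a, n_out)
  b <- rep_len(cfg$ses_gradient_b, n_out)
  assert_that(is_prob(a), "`baseline_a` must lie in [0, 1]",
              "equicover_invalid_config")
  assert_that(all(is.finite(b)) && all(a + b >= 0) && all(a + b <= 1),
              "`baseline_a + ses_gradient_b` must lie in [0, 1]",
              "equicover_invalid_config")
  assert_that(is_prob(rep_len(cfg$missing_rate, n_out)),
              "`missing_rate` must lie in [0, 1]", "equicover_invalid_config")
  assert_that(is.numeric(cfg$weight_dispersion) && cfg$weight_dispersion >= 0,
              "`weight_dispersion` must be non-negative", "equicover_invalid_config")
  assert_that(cfg$ea_frame_size >= cfg$n_ea_per_stratum,
              "`ea_frame_size` must be at least `n_ea_per_stratum`",
              "equicover_invalid_config")
  assert_that(cfg$hh_frame_size >= cfg$households_per_ea,
              "`hh_frame_size` must be at least `households_per_ea`",
              "equicover_invalid_config")
  invisible(cfg)
}

#' Generate households under the multistage stratified design
#'
#' Draws the household frame implied by a [generator_config()]: every
#' province x locality stratum contributes `n_ea_per_stratum` EAs of
#' `households_per_ea` households. Each household receives a latent
#' living-standards score (standard logistic, so the asset battery behaves as
#' a Rasch-type item set with closed-form item prevalences), binary asset
#' indicators owned with probability `plogis(latent_ses - difficulty)`, and a
#' design weight equal to the inverse product of the two stage-selection
#' probabilities, jittered by a mean-one multiplicative log-normal factor
#' with standard deviation `weight_dispersion` on the log scale.
#'
#' @param config A [generator_config()].
#' @return Data frame with one row per household: `household_id`, `province`,
#'   `locality`, `stratum_id`, `ea_id`, `latent_ses`, one 0/1 column per
#'   asset item, and `design_weight`.
#' @export
generate_households <- function(config) {
  validate_generator_config(config)
  with_seed(config$seed, {
    provinces <- sprintf("P%02d", seq_len(config$n_provinces))
    strata <- expand.grid(province = provinces, locality = config$locality_labels,
                          stringsAsFactors = FALSE)
    strata$stratum_id <- paste(strata$province, strata$locality, sep = "|")
    n_strata <- nrow(strata)
    ea_per <- config$n_ea_per_stratum
    hh_per <- config$households_per_ea
    n_hh <- n_strata * ea_per * hh_per

    stratum_idx <- rep(seq_len(n_strata), each = ea_per * hh_per)
    ea_within <- rep(rep(seq_len(ea_per), each = hh_per), times = n_strata)
    hh <- data.frame(
      household_id = sprintf("H%06d", seq_len(n_hh)),
      province = strata$province[stratum_idx],
      locality = strata$locality[stratum_idx],
      stratum_id = strata$stratum_id[stratum_idx],
      stringsAsFactors = FALSE
    )
    hh$ea_id <- sprintf("%s|EA%03d", hh$stratum_id, ea_within)
    # localities differ systematically in living standards
    loc_shift <- stats::setNames(
      seq(1, -1, length.out = length(config$locality_labels)),
      config$locality_labels)
    hh$latent_ses <- stats::rlogis(n_hh) + loc_shift[hh$locality]
    for (j in seq_along(config$asset_items)) {
      pj <- stats::plogis(hh$latent_ses - config$asset_items[j])
      hh[[names(config$asset_items)[j]]] <- stats::rbinom(n_hh, 1, pj)
    }
    p1 <- ea_per / config$ea_frame_size
    p2 <- hh_per / config$hh_frame_size
    base_w <- 1 / (p1 * p2)
    sigma <- config$weight_dispersion
    jitter <- if (sigma > 0) {
      exp(stats::rnorm(n_hh, -sigma^2 / 2, sigma))  # mean-one multiplicative
    } else {
      rep(1, n_hh)
    }
    hh$design_weight <- base_w * jitter
    hh
  })
}

#' Kish-style selection of one member per age band
#'
#' Selects exactly one member uniformly at random within each occupied age
#' band of a household roster, emulating a Kish selection grid. An empty
#' roster yields an empty selection.
#'
#' @param roster Data frame with at least a `member_id` and an `age_band`
#'   column.
#' @param seed Optional integer seed making the selection deterministic.
#' @return The selected rows of `roster`, one per occupied band, with a
#'   `band_size` column giving the number of members the band held (the
#'   inverse of the within-band selection probability).
#' @export
kish_select <- function(roster, seed = NULL) {
  assert_that(is.data.frame(roster) && "age_band" %in% names(roster),
              "`roster` must be a data frame with an `age_band` column",
              "equicover_invalid_config")
  if (nrow(roster) == 0) {
    out <- roster
    out$band_size <- integer(0)
    return(out)
  }
  with_seed(seed, {
    picks <- lapply(split(seq_len(nrow(roster)), roster$age_band, drop = TRUE),
                    function(idx) {
                      c(idx[sample.int(length(idx), 1L)], length(idx))
                    })
    sel <- vapply(picks, `[`, 1L, 1L)
    out <- roster[sel, , drop = FALSE]
    out$band_size <- vapply(picks, `[`, 1L, 2L)
    rownames(out) <- NULL
    out[order(out$age_band), , drop = FALSE]
  })
}

# age bands of eligible women and the expected number per household per band
.age_bands <- c("15-19", "20-29", "30-39", "40-54")
.band_rates <- c(0.25, 0.45, 0.35, 0.25)

#' Generate individual women with outcomes from a household frame
#'
#' Builds a within-household roster of eligible women (Poisson counts per age
#' band), applies Kish-style selection of one woman per occupied band, and
#' draws each binary outcome as Bernoulli with probability
#' `baseline_a + ses_gradient_b * F`, where `F` is the design-weighted
#' empirical midpoint rank (in \[0, 1\]) of the woman's household latent
#' living-standards score. The analysis weight is the household design weight
#' multiplied by the occupied band size (the inverse within-band selection
#' probability). Equity-stratifier variables (province, locality, race,
#' education, employment, household headship, HIV status) are populated from
#' the stratum labels and SES-correlated draws.
#'
#' @param households Output of [generate_households()].
#' @param config The same [generator_config()].
#' @return Data frame with one row per selected woman: identifiers, design
#'   columns (`stratum_id`, `ea_id`, `analysis_weight`), `age_band`,
#'   stratifier columns, and one 0/1 (or `NA`) column per outcome.
#' @export
generate_outcomes <- function(households, config) {
  validate_generator_config(config)
  with_seed(config$seed + 1L, {
    n_hh <- nrow(households)
    counts <- sapply(.band_rates, function(l) stats::rpois(n_hh, l))
    occupied <- counts >= 1
    hh_idx <- rep(seq_len(n_hh), times = rowSums(occupied))
    band <- unlist(apply(occupied, 1, which, simplify = FALSE), use.names = FALSE)
    band_size <- counts[cbind(hh_idx, band)]
    n_w <- length(hh_idx)
    if (n_w == 0) abort("no eligible women generated; enlarge the design",
                        "equicover_invalid_config")

    # design-weighted midpoint rank of household latent SES
    w_hh <- households$design_weight
    ord <- order(households$latent_ses)
    cw <- cumsum(w_hh[ord])
    F_hh <- numeric(n_hh)
    F_hh[ord] <- (cw - w_hh[ord] / 2) / sum(w_hh)

    women <- data.frame(
      woman_id = sprintf("W%06d", seq_len(n_w)),
      household_id = households$household_id[hh_idx],
      stratum_id = households$stratum_id[hh_idx],
      ea_id = households$ea_id[hh_idx],
      province = households$province[hh_idx],
      locality = households$locality[hh_idx],
      age_band = .age_bands[band],
      stringsAsFactors = FALSE
    )
    women$analysis_weight <- households$design_weight[hh_idx] * band_size

    ses <- households$latent_ses[hh_idx]
    rank_ses <- F_hh[hh_idx]
    # stratifiers correlated with living standards, as in real surveys
    race_lv <- c("African", "Mixed ancestry", "White", "Indian")
    race_p <- function(f) cbind(0.97 - 0.45 * f, 0.02 + 0.10 * f,
                                0.005 + 0.28 * f, 0.005 + 0.07 * f)
    rp <- race_p(rank_ses)
    women$race <- race_lv[max.col(log(rp) + matrix(-log(-log(stats::runif(n_w * 4))),
                                                   n_w, 4))]
    edu_lv <- c("none/primary", "incomplete secondary", "complete secondary",
                "tertiary")
    edu_score <- ses + stats::rlogis(n_w)
    women$education <- edu_lv[findInterval(edu_score, c(-1.2, 1, 2.8)) + 1L]
    women$employed <- stats::rbinom(n_w, 1, stats::plogis(-2 + 2.5 * rank_ses))
    women$household_head <- stats::rbinom(n_w, 1, 0.11)
    women$hiv_positive <- stats::rbinom(n_w, 1, stats::plogis(-0.6 - 1.2 * rank_ses))

    n_out <- length(config$outcome_names)
    a <- rep_len(config$baseline_a, n_out)
    b <- rep_len(config$ses_gradient_b, n_out)
    miss <- rep_len(config$missing_rate, n_out)
    for (j in seq_len(n_out)) {
      p <- a[j] + b[j] * rank_ses
      assert_that(all(p >= 0) && all(p <= 1),
                  "outcome probability outside [0, 1]", "equicover_invalid_config")
      yj <- stats::rbinom(n_w, 1, p)
      if (miss[j] > 0) yj[stats::runif(n_w) < miss[j]] <- NA
      women[[config$outcome_names[j]]] <- yj
    }
    women$latent_ses <- ses
    women$ses_rank <- rank_ses
    women
  })
}

#' Rake analysis weights to target margins (iterative proportional fitting)
#'
#' Adjusts weights so the weighted distribution of each raking variable
#' matches supplied target population shares, cycling through the dimensions
#' until the largest relative margin discrepancy falls below `tol` or
#' `max_iter` is reached. The total weight is preserved. Weights stay
#' positive throughout.
#'
#' @param weights Positive starting weights.
#' @param vars Data frame of raking variables (e.g. age band, race,
#'   province), one row per record.
#' @param margins Named list (one element per column of `vars`) of named
#'   target share vectors, each summing to 1.
#' @param tol Convergence tolerance on the maximum relative discrepancy.
#' @param max_iter Maximum number of full IPF cycles.
#' @return Numeric vector of adjusted weights with attributes `iterations`
#'   and `max_discrepancy`.
#' @export
rake_weights <- function(weights, vars, margins, tol = 1e-6, max_iter = 50) {
  assert_that(all(weights > 0), "starting weights must be positive",
              "equicover_raking_failure")
  assert_that(is.data.frame(vars) && nrow(vars) == length(weights),
              "`vars` must align with `weights`", "equicover_raking_failure")
  assert_that(all(names(margins) %in% names(vars)),
              "every margin must name a column of `vars`", "equicover_raking_failure")
  for (m in names(margins)) {
    tgt <- margins[[m]]
    assert_that(abs(sum(tgt) - 1) < 1e-6,
                sprintf("target shares for '%s' must sum to 1", m),
                "equicover_raking_failure")
    obs_lv <- unique(as.character(vars[[m]]))
    missing_cat <- setdiff(names(tgt)[tgt > 0], obs_lv)
    if (length(missing_cat)) {
      abort(sprintf("raking failure: no records in '%s' category %s with positive target",
                    m, paste(missing_cat, collapse = ", ")),
            "equicover_raking_failure")
    }
    unmatched <- setdiff(obs_lv, names(tgt))
    if (length(unmatched)) {
      abort(sprintf("raking failure: '%s' categories %s lack a target share",
                    m, paste(unmatched, collapse = ", ")),
            "equicover_raking_failure")
    }
  }
  w <- weights
  total <- sum(weights)
  disc <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (m in names(margins)) {
      tgt <- margins[[m]]
      f <- as.character(vars[[m]])
      cur <- tapply(w, f, sum) / sum(w)
      adj <- tgt[f] / as.numeric(cur[f])
      w <- w * adj
    }
    w <- w * total / sum(w)
    disc <- max(vapply(names(margins), function(m) {
      cur <- tapply(w, as.character(vars[[m]]), sum) / sum(w)
      tgt <- margins[[m]][names(cur)]
      max(abs(cur - tgt) / pmax(tgt, .Machine$double.eps))
    }, numeric(1)))
    if (disc < tol) break
  }
  structure(w, iterations = it, max_discrepancy = disc)
}

#' Closed-form true equity parameters implied by a generator configuration
#'
#' Under the linear-in-rank outcome model \eqn{\Pr(y=1) = a + bF} with equal-
#' share groups, the group means lie exactly on a line in the group midpoint
#' ranks, so the population slope index of inequality equals `b`; the
#' population mean is \eqn{\mu = a + b/2} (the rank is uniform on \[0, 1\]);
#' the relative index is \eqn{b/\mu}; and the grouped concentration index is
#' \eqn{2 b \,\mathrm{Var}(r)/\mu} with \eqn{\mathrm{Var}(r)} the variance of
#' the k equal-group midpoint ranks (0.078125 for quartiles).
#'
#' @param config A [generator_config()].
#' @param k Number of equal-share socio-economic groups (default 4).
#' @return Data frame of class `"synthetic_truth"`, one row per outcome, with
#'   columns `outcome`, `true_mu`, `true_sii`, `true_rii`, `true_c_grouped`,
#'   and the group ranks as attribute `group_ranks`.
#' @export
true_equity_values <- function(config, k = 4) {
  validate_generator_config(config)
  assert_that(is_count(k) && k >= 2, "`k` must be an integer >= 2",
              "equicover_invalid_config")
  n_out <- length(config$outcome_names)
  a <- rep_len(config$baseline_a, n_out)
  b <- rep_len(config$ses_gradient_b, n_out)
  r <- (2 * seq_len(k) - 1) / (2 * k)
  var_r <- mean(r^2) - mean(r)^2
  mu <- a + b / 2
  assert_that(all(mu > 0 | b == 0), "relative indices undefined at zero mean",
              "equicover_unsupported_config")
  out <- data.frame(outcome = config$outcome_names, true_mu = mu, true_sii = b,
                    true_rii = ifelse(mu > 0, b / mu, 0),
                    true_c_grouped = ifelse(mu > 0, 2 * b * var_r / mu, 0))
  attr(out, "group_ranks") <- r
  class(out) <- c("synthetic_truth", class(out))
  out
}

#' Simulate a complete synthetic survey
#'
#' Runs [generate_households()] and [generate_outcomes()], optionally rakes
#' the women's analysis weights to target margins, and attaches the
#' closed-form truth from [true_equity_values()].
#'
#' @param config A [generator_config()].
#' @param rake_margins Optional named list of target share vectors (by e.g.
#'   `age_band`, `race`, `province`) passed to [rake_weights()].
#' @return List of class `"synthetic_survey"` with elements `households`,
#'   `women`, `truth` and `config`.
#' @export
simulate_survey <- function(config, rake_margins = NULL) {
  households <- generate_households(config)
  women <- generate_outcomes(households, config)
  if (!is.null(rake_margins)) {
    women$analysis_weight <- as.numeric(rake_weights(
      women$analysis_weight, women[names(rake_margins)], rake_margins))
  }
  structure(list(households = households, women = women,
                 truth = true_equity_values(config), config = config),
            class = "synthetic_survey")
}

#' Write a synthetic survey to disk in the pipeline's CSV dialect
#'
#' Emits `households.csv`, `women.csv`, `truth.json` and `config.json` so
#' generated fixtures are first-class pipeline inputs.
#'
#' @param sim A [simulate_survey()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("households.csv", "women.csv", "truth.json",
                            "config.json"))
  utils::write.csv(sim$households, paths[1], row.names = FALSE)
  utils::write.csv(sim$women, paths[2], row.names = FALSE)
  jsonlite::write_json(as.list(sim$truth), paths[3], auto_unbox = TRUE, digits = NA)
  cfg <- sim$config
  cfg$asset_items <- as.list(cfg$asset_items)
  jsonlite::write_json(unclass(cfg), paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
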