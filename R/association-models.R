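#' Specification of a survey-weighted logistic model
#'
#' Names the binary outcome, the candidate categorical covariates with their
#' reference levels, and the backward-elimination threshold.
#'
#' @param outcome Name of the binary outcome column.
#' @param covariates Character vector of categorical covariate columns, in
#'   the order used to break elimination ties.
#' @param ref_levels Optional named character vector of reference levels
#'   (default: first factor level of each covariate).
#' @param alpha Retention threshold for backward elimination (covariates with
#'   joint Wald p-value above `alpha` are candidates for removal).
#' @return List of class `"model_spec"`.
#' @export
model_spec <- function(outcome, covariates, ref_levels = NULL, alpha = 0.05) {
  assert_that(is.character(outcome) && length(outcome) == 1L,
              "`outcome` must be a single column name", "equicover_spec_error")
  assert_that(is.character(covariates) && length(covariates) >= 1L,
              "`covariates` must name at least one column", "equicover_spec_error")
  assert_that(is.numeric(alpha) && alpha > 0 && alpha <= 1,
              "`alpha` must lie in (0, 1]", "equicover_spec_error")
  structure(list(outcome = outcome, covariates = covariates,
                 ref_levels = ref_levels, alpha = alpha),
            class = "model_spec")
}

#' Survey-weighted logistic regression with design-based standard errors
#'
#' Fits a logistic model by maximum pseudo-likelihood (iteratively reweighted
#' least squares with the analysis weights). Variances are by a linearised
#' sandwich whose meat accumulates score totals over PSUs within strata; with
#' `cluster_se = FALSE` a model-based (binomial information) variance is used
#' instead, the stance appropriate when clustering is ignored. Covariate
#' categories in which the outcome does not vary (separation: no failures or
#' no successes) are detected, flagged, and their records omitted from the
#' fit, so the reported odds ratios stay finite.
#'
#' @param spec A [model_spec()].
#' @param data Data frame holding the outcome and covariate columns.
#' @param design A [survey_design()] aligned with `data`.
#' @param cluster_se Cluster the sandwich on PSUs within strata (default
#'   TRUE); FALSE gives model-based standard errors.
#' @param conf_level Confidence level for odds-ratio intervals.
#' @return Object of class `"logit_fit"`: list with `table` (term, level,
#'   estimate, se, odds ratio, CI), `omitted` (separated categories),
#'   `coefficients`, `vcov`, `converged`, and the covariates fitted.
#' @export
weighted_logit_fit <- function(spec, data, design, cluster_se = TRUE,
                               conf_level = 0.95) {
  stopifnot(inherits(spec, "model_spec"), inherits(design, "survey_design"))
  cols <- c(spec$outcome, spec$covariates)
  assert_that(all(cols %in% names(data)),
              paste("missing columns:", paste(setdiff(cols, names(data)), collapse = ", ")),
              "equicover_spec_error")
  keep <- stats::complete.cases(data[cols])
  df <- data[keep, cols, drop = FALSE]
  w <- design$weight[keep]
  stratum <- design$stratum[keep]
  psu <- design$psu[keep]
  y <- df[[spec$outcome]]
  assert_that(all(y %in% c(0, 1)), "outcome must be binary 0/1",
              "equicover_invalid_outcome")
  if (length(unique(y)) < 2) {
    abort("outcome is constant: model degenerate", "equicover_degenerate_outcome")
  }
  # mean-one weights: estimates are invariant to the weight scale and the
  # IRLS deviance criterion behaves at survey-scale weights
  w <- w / mean(w)
  for (v in spec$covariates) {
    f <- factor(df[[v]], ordered = FALSE)  # treatment contrasts throughout
    ref <- spec$ref_levels[[v]]
    if (!is.null(ref)) {
      assert_that(ref %in% levels(f),
                  sprintf("reference level '%s' absent from '%s'", ref, v),
                  "equicover_spec_error")
      f <- stats::relevel(f, ref)
    }
    df[[v]] <- f
  }

  # separation scan: categories where the outcome never varies are omitted
  omitted <- list()
  drop_row <- rep(FALSE, nrow(df))
  for (v in spec$covariates) {
    for (lv in levels(df[[v]])) {
      sel <- df[[v]] == lv
      if (any(sel) && length(unique(y[sel])) < 2) {
        omitted[[length(omitted) + 1L]] <- data.frame(term = v, level = lv)
        drop_row <- drop_row | sel
      }
    }
  }
  if (any(drop_row)) {
    df <- df[!drop_row, , drop = FALSE]
    w <- w[!drop_row]; stratum <- stratum[!drop_row]; psu <- psu[!drop_row]
    y <- df[[spec$outcome]]
    df[spec$covariates] <- lapply(df[spec$covariates], droplevels)
    if (length(unique(y)) < 2) {
      abort("outcome constant after omitting separated categories",
            "equicover_degenerate_outcome")
    }
  }

  fml <- stats::reformulate(spec$covariates, response = spec$outcome)
  fit <- suppressWarnings(stats::glm(fml, family = stats::quasibinomial(),
                                     data = df, weights = w,
                                     control = stats::glm.control(epsilon = 1e-8,
                                                                  maxit = 50)))
  if (!fit$converged) {
    abort("IRLS failed to converge within 50 iterations", "equicover_convergence")
  }
  beta <- stats::coef(fit)
  X <- stats::model.matrix(fit)
  mu <- stats::fitted(fit)
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  bread <- solve(info)
  if (cluster_se) {
    U <- X * (w * (y - mu))                       # per-record score rows
    key <- paste(stratum, psu, sep = "\r")
    G <- rowsum(U, key, reorder = FALSE)          # PSU score totals
    h_of <- tapply(stratum, key, function(s) s[1])[rownames(G)]
    meat <- matrix(0, ncol(X), ncol(X))
    for (h in unique(h_of)) {
      Gh <- G[h_of == h, , drop = FALSE]
      nh <- nrow(Gh)
      if (nh < 2) next
      Gc <- sweep(Gh, 2, colMeans(Gh))
      meat <- meat + nh / (nh - 1) * crossprod(Gc)
    }
    V <- bread %*% meat %*% bread
  } else {
    V <- bread
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(V))
  terms_of <- attr(X, "assign")
  term_lab <- c("(Intercept)", spec$covariates)[terms_of + 1L]
  tab <- data.frame(
    term = term_lab,
    coefficient = names(beta),
    estimate = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    or_low = exp(unname(beta - zq * se)),
    or_high = exp(unname(beta + zq * se)),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 omitted = if (length(omitted)) do.call(rbind, omitted),
                 coefficients = beta, vcov = V, assign = terms_of,
                 covariates = spec$covariates, outcome = spec$outcome,
                 converged = fit$converged, n = nrow(df),
                 ref_levels = lapply(df[spec$covariates], function(f) levels(f)[1]),
                 levels = lapply(df[spec$covariates], levels)),
            class = "logit_fit")
}

# joint Wald test (chi-square) for all coefficients of one covariate
wald_joint_p <- function(fit, covariate) {
  idx <- which(fit$assign == match(covariate, fit$covariates))
  if (!length(idx)) return(NA_real_)
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- tryCatch(as.numeric(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(stat)) return(NA_real_)
  stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
}

#' Backward elimination over a survey-weighted logistic model
#'
#' Repeatedly refits the model, each time removing the covariate with the
#' largest joint Wald p-value (all its levels tested together, so multi-level
#' factors enter and leave whole) exceeding `spec$alpha`, until every
#' remaining covariate is retained. Ties are broken by the declared covariate
#' order. Deterministic given the data and threshold.
#'
#' @inheritParams weighted_logit_fit
#' @return List with `fit` (the final [weighted_logit_fit()]), `retained`,
#'   and `log` (data frame of elimination steps with their p-values).
#' @export
backward_eliminate <- function(spec, data, design, cluster_se = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  current <- spec$covariates
  log_steps <- list()
  repeat {
    sub <- model_spec(spec$outcome, current, spec$ref_levels, spec$alpha)
    fit <- weighted_logit_fit(sub, data, design, cluster_se = cluster_se)
    pvals <- vapply(current, function(v) wald_joint_p(fit, v), numeric(1))
    if (all(!is.finite(pvals))) break
    worst_p <- max(pvals, na.rm = TRUE)
    if (worst_p <= spec$alpha) break
    drop <- current[which(pvals >= worst_p - 1e-12)[1]]  # declared-order tie-break
    log_steps[[length(log_steps) + 1L]] <-
      data.frame(step = length(log_steps) + 1L, dropped = drop, p_value = worst_p)
    current <- setdiff(current, drop)
    if (!length(current)) break
  }
  final <- if (length(current)) {
    weighted_logit_fit(model_spec(spec$outcome, current, spec$ref_levels,
                                  spec$alpha), data, design,
                       cluster_se = cluster_se)
  }
  list(fit = final, retained = current,
       log = if (length(log_steps)) do.call(rbind, log_steps) else
         data.frame(step = integer(), dropped = character(), p_value = numeric()))
}

#' Combined unadjusted / adjusted odds-ratio table
#'
#' One row per covariate level across a set of single-covariate (unadjusted)
#' fits and one multivariable (adjusted) fit. Reference levels print an odds
#' ratio of 1; covariates eliminated from the adjusted model leave blank
#' adjusted cells; categories omitted for separation are marked `"#"`.
#'
#' @param unadjusted Named list of `"logit_fit"` objects, one per covariate.
#' @param adjusted A `"logit_fit"` (or `NULL`), e.g. from
#'   [backward_eliminate()].
#' @param digits Decimals for the formatted odds-ratio strings.
#' @return Data frame with columns `term`, `level`, `or_unadjusted`,
#'   `or_adjusted` (formatted "OR (low-high)" strings, `""` when absent,
#'   `"#"` when omitted) plus the numeric columns.
#' @export
or_table <- function(unadjusted, adjusted = NULL, digits = 2) {
  fmt <- function(or, lo, hi) {
    ifelse(is.na(or), "",
           sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
                   or, lo, hi))
  }
  rows <- list()
  for (v in names(unadjusted)) {
    fit_u <- unadjusted[[v]]
    assert_that(v %in% fit_u$covariates,
                sprintf("unadjusted fit for '%s' does not contain it", v),
                "equicover_spec_error")
    levs <- fit_u$levels[[v]]
    if (!is.null(adjusted) && v %in% adjusted$covariates) {
      ref_a <- adjusted$ref_levels[[v]]
      assert_that(identical(fit_u$ref_levels[[v]], ref_a),
                  sprintf("reference level mismatch for '%s'", v),
                  "equicover_spec_error")
      levs <- union(levs, adjusted$levels[[v]])
    }
    omitted_u <- if (!is.null(fit_u$omitted)) {
      fit_u$omitted$level[fit_u$omitted$term == v]
    } else {
      character(0)
    }
    omitted_a <- if (!is.null(adjusted) && !is.null(adjusted$omitted)) {
      adjusted$omitted$level[adjusted$omitted$term == v]
    } else {
      character(0)
    }
    pull <- function(fit, lv) {
      if (is.null(fit) || !(v %in% fit$covariates)) return(rep(NA_real_, 3))
      if (lv == fit$ref_levels[[v]]) return(c(1, NA, NA))
      row <- fit$table[fit$table$term == v &
                         fit$table$coefficient == paste0(v, lv), ]
      if (!nrow(row)) return(rep(NA_real_, 3))
      c(row$or, row$or_low, row$or_high)
    }
    levs <- union(levs, c(omitted_u, omitted_a))
    for (lv in levs) {
      u <- pull(fit_u, lv)
      a <- pull(adjusted, lv)
      is_ref <- !is.na(u[1]) && is.na(u[2]) && u[1] == 1
      rows[[length(rows) + 1L]] <- data.frame(
        term = v, level = lv,
        or_unadjusted = if (lv %in% omitted_u) "#" else if (is_ref) "1.0" else
          fmt(u[1], u[2], u[3]),
        or_adjusted = if (lv %in% omitted_a) "#" else
          if (!is.null(adjusted) && v %in% adjusted$covariates) {
            if (!is.na(a[1]) && is.na(a[2]) && a[1] == 1) "1.0" else
              fmt(a[1], a[2], a[3])
          } else "",
        or_u = u[1], or_u_low = u[2], or_u_high = u[3],
        or_a = a[1], or_a_low = a[2], or_a_high = a[3],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
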