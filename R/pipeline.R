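#' Configuration for a full pipeline run
#'
#' Either simulates a survey (via a [generator_config()]) or reads
#' `households.csv` / `women.csv` from `input_dir`, then declares how the
#' downstream stages find their columns: the design mapping (stratum, PSU,
#' weight), the asset battery, the outcomes with their analysis domains, the
#' equity stratifier variables, and the modelling stage.
#'
#' @param simulate Optional [generator_config()]; mutually exclusive with
#'   `input_dir`.
#' @param input_dir Optional directory holding `households.csv` and
#'   `women.csv`.
#' @param design Named list mapping `stratum`, `psu` and `weight` to column
#'   names of the women table (`psu = NULL` ignores clustering).
#' @param asset_cols Character vector of asset columns in the household
#'   table (default: columns starting with `"asset_"`).
#' @param outcomes Character vector of binary outcome columns in the women
#'   table.
#' @param domains Optional named list mapping an outcome to the name of a 0/1
#'   domain-membership column (analysis restricted to that domain).
#' @param groupings Character vector of stratifier columns for the grouped
#'   tabulations (e.g. province, locality, race, education).
#' @param k Number of socio-economic groups (default 4).
#' @param model_covariates Optional character vector of covariates for the
#'   odds-ratio stage (`NULL` skips it); the socio-economic group is always
#'   included as `"seq_group"`.
#' @param alpha Backward-elimination threshold.
#' @param boot Bootstrap replicates for equity-index intervals.
#' @param seed Integer seed for all stochastic stages.
#' @param ignore_clustering Treat records as independent for variance
#'   estimation (replication stance for designs with very many PSUs).
#' @param weighted_mca Use survey weights in the MCA row masses.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            design = list(stratum = "stratum_id",
                                          psu = "ea_id",
                                          weight = "analysis_weight"),
                            asset_cols = NULL,
                            outcomes = NULL,
                            domains = NULL,
                            groupings = c("province", "locality"),
                            k = 4,
                            model_covariates = NULL,
                            alpha = 0.05,
                            boot = 1000,
                            seed = 1L,
                            ignore_clustering = FALSE,
                            weighted_mca = TRUE) {
  assert_that(xor(is.null(simulate), is.null(input_dir)),
              "exactly one of `simulate` or `input_dir` must be given",
              "equicover_invalid_config")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "generator_config"))
  assert_that(is.list(design) && !is.null(design$weight),
              "`design` must map at least the weight column",
              "equicover_invalid_config")
  structure(list(simulate = simulate, input_dir = input_dir, design = design,
                 asset_cols = asset_cols, outcomes = outcomes,
                 domains = domains, groupings = groupings, k = k,
                 model_covariates = model_covariates, alpha = alpha,
                 boot = boot, seed = as.integer(seed),
                 ignore_clustering = ignore_clustering,
                 weighted_mca = weighted_mca),
            class = "pipeline_config")
}

read_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- simulate_survey(config$simulate)
    list(households = sim$households, women = sim$women, truth = sim$truth)
  } else {
    hp <- file.path(config$input_dir, "households.csv")
    wp <- file.path(config$input_dir, "women.csv")
    assert_that(file.exists(hp) && file.exists(wp),
                "input_dir must contain households.csv and women.csv",
                "equicover_invalid_config")
    list(households = utils::read.csv(hp, stringsAsFactors = FALSE),
         women = utils::read.csv(wp, stringsAsFactors = FALSE), truth = NULL)
  }
}

check_schema <- function(config, households, women) {
  asset_cols <- config$asset_cols
  if (is.null(asset_cols)) {
    asset_cols <- grep("^asset_", names(households), value = TRUE)
  }
  assert_that(length(asset_cols) >= 1L && all(asset_cols %in% names(households)),
              "asset columns not found in household table", "equicover_invalid_config")
  outcomes <- config$outcomes
  if (is.null(outcomes) && !is.null(config$simulate)) {
    outcomes <- config$simulate$outcome_names
  }
  assert_that(!is.null(outcomes) && all(outcomes %in% names(women)),
              "outcome columns not found in women table", "equicover_invalid_config")
  need <- c(config$design$weight,
            if (!config$ignore_clustering) config$design$psu,
            config$design$stratum, config$groupings,
            unlist(config$domains))
  miss <- setdiff(need[!vapply(need, is.null, TRUE)], names(women))
  assert_that(length(miss) == 0,
              paste("columns missing from women table:", paste(miss, collapse = ", ")),
              "equicover_invalid_config")
  list(asset_cols = asset_cols, outcomes = outcomes)
}

#' Run the full equity-analysis pipeline
#'
#' Stages, in order: obtain data (simulate or read), build the asset-based
#' wealth index and socio-economic groups on the household table, join the
#' groups onto the women table, tabulate weighted outcome prevalences across
#' the socio-economic groups and every declared stratifier (with Rao-Scott
#' tests), compute the equity indices with bootstrap intervals, and (when
#' covariates are declared) fit unadjusted and backward-eliminated adjusted
#' odds-ratio models. Deterministic given the configuration's seeds.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"report_bundle"`: list with `composition`
#'   (population composition by socio-economic group), `equity` (one row per
#'   outcome with prevalences, gap, RII, SII, C and intervals),
#'   `equity_results` (the full [equity_indices()] objects), `or_tables`,
#'   `max_gaps`, `grouped` (per-stratifier grouped tables), and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- read_pipeline_inputs(config)
  households <- inputs$households
  women <- inputs$women
  schema <- check_schema(config, households, women)

  # stage 1: wealth index on the household asset battery
  wi <- wealth_index(households[schema$asset_cols],
                     weights = households$design_weight,
                     k = config$k, weighted_mca = config$weighted_mca)
  households$wealth_score <- wi$score
  households$seq_group <- wi$group

  # stage 2: join socio-economic groups onto individual records
  idx <- match(women$household_id, households$household_id)
  assert_that(!anyNA(idx), "women reference unknown household_id",
              "equicover_invalid_config")
  women$seq_group <- households$seq_group[idx]
  women$wealth_score <- households$wealth_score[idx]

  design <- survey_design(
    weight = women[[config$design$weight]],
    stratum = if (!is.null(config$design$stratum)) women[[config$design$stratum]],
    psu = if (!config$ignore_clustering && !is.null(config$design$psu)) {
      women[[config$design$psu]]
    }
  )

  # stage 3: population composition by socio-economic group
  composition <- lapply(config$groupings, function(g) {
    lv <- sort(unique(stats::na.omit(women[[g]])))
    do.call(rbind, lapply(lv, function(v) {
      go <- grouped_prevalence(as.numeric(women[[g]] == v), women$seq_group, design)
      data.frame(grouping = g, category = as.character(v),
                 t(stats::setNames(round(100 * go$prevalence, 1), go$group)),
                 overall = round(100 * attr(go, "mu"), 1),
                 check.names = FALSE)
    }))
  })
  composition <- do.call(rbind, composition)

  # stage 4: equity indices per outcome across socio-economic groups
  equity_results <- list()
  equity_rows <- list()
  grouped_tables <- list()
  for (i in seq_along(schema$outcomes)) {
    oc <- schema$outcomes[i]
    dom <- if (!is.null(config$domains[[oc]])) women[[config$domains[[oc]]]] == 1
    er <- equity_indices(women[[oc]], women$seq_group, design, domain = dom,
                         boot = config$boot, seed = config$seed + i,
                         percent = TRUE)
    er$outcome <- oc
    rs <- rao_scott_f(women[[oc]], women$seq_group, design, domain = dom)
    g <- er$grouped
    cb <- function(which, i) if (is.null(er$ci)) NA_real_ else er$ci[[which]][i]
    row <- data.frame(outcome = oc,
                      t(stats::setNames(round(100 * g$prevalence, 1), g$group)),
                      overall = round(er$mu, 1), n = sum(g$n),
                      gap = round(er$gap, 1),
                      rii = round(er$rii, 2),
                      rii_low = round(cb("rii", 1), 2),
                      rii_high = round(cb("rii", 2), 2),
                      sii = round(er$sii, 1),
                      sii_low = round(cb("sii", 1), 1),
                      sii_high = round(cb("sii", 2), 1),
                      concentration_index = round(er$concentration_index, 4),
                      rao_scott_p = rs$p_value,
                      check.names = FALSE)
    equity_results[[oc]] <- er
    equity_rows[[oc]] <- row
    # grouped prevalences across every stratifier, for the gap table
    grouped_tables[[oc]] <- lapply(
      stats::setNames(c("seq_group", config$groupings),
                      c("seq_group", config$groupings)),
      function(g) grouped_prevalence(women[[oc]], women[[g]], design, domain = dom))
  }
  equity <- do.call(rbind, equity_rows)

  # stage 5: association models (optional)
  or_tables <- NULL
  elimination_logs <- NULL
  if (!is.null(config$model_covariates)) {
    or_tables <- list()
    elimination_logs <- list()
    covs <- unique(c("seq_group", config$model_covariates))
    for (oc in schema$outcomes) {
      women_oc <- women
      women_oc[covs] <- lapply(women_oc[covs], function(x) factor(x))
      unadj <- lapply(stats::setNames(covs, covs), function(v) {
        weighted_logit_fit(model_spec(oc, v), women_oc, design,
                           cluster_se = !config$ignore_clustering)
      })
      be <- backward_eliminate(model_spec(oc, covs, alpha = config$alpha),
                               women_oc, design,
                               cluster_se = !config$ignore_clustering)
      or_tables[[oc]] <- or_table(unadj, be$fit)
      elimination_logs[[oc]] <- be$log
    }
  }

  max_gaps <- max_gap_table(grouped_tables)

  bundle <- list(
    composition = composition,
    equity = equity,
    equity_results = equity_results,
    or_tables = or_tables,
    elimination_logs = elimination_logs,
    max_gaps = max_gaps,
    grouped = grouped_tables,
    truth = inputs$truth,
    provenance = list(config_hash = object_hash(unclass(config)),
                      seed = config$seed, k = config$k, boot = config$boot,
                      package_version = as.character(utils::packageVersion("equicover")))
  )
  class(bundle) <- "report_bundle"
  bundle
}

#' Extreme-group gaps for every stratifier and outcome
#'
#' For each grouping variable and outcome, the absolute percentage-point
#' difference between the highest and lowest group prevalence (`max - min`),
#' and — since for ordered groupings published tables sometimes report the
#' top-versus-bottom category instead — the `last - first` difference as a
#' separate column. Groupings with fewer than two estimated groups are
#' excluded with a warning.
#'
#' @param grouped_tables Nested list: outcome -> grouping ->
#'   [grouped_outcome()].
#' @return Data frame with columns `outcome`, `grouping`, `max_minus_min`,
#'   `top_minus_bottom` (percentage points, one decimal).
#' @export
max_gap_table <- function(grouped_tables) {
  rows <- list()
  for (oc in names(grouped_tables)) {
    for (g in names(grouped_tables[[oc]])) {
      go <- grouped_tables[[oc]][[g]]
      if (nrow(go) < 2) {
        warning(sprintf("grouping '%s' has a single group for '%s'; excluded",
                        g, oc), call. = FALSE)
        next
      }
      h <- 100 * go$prevalence
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, grouping = g,
        max_minus_min = round(max(h) - min(h), 1),
        top_minus_bottom = round(h[length(h)] - h[1], 1))
    }
  }
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' Emits one CSV per table (composition, equity, odds ratios, gaps), a JSON
#' twin of the bundle's numeric content, and a provenance file. Output is
#' deterministic: two runs from the same seeds produce byte-identical files.
#'
#' @param bundle A `"report_bundle"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$composition)) emit_csv(bundle$composition, "composition.csv")
  if (!is.null(bundle$equity)) emit_csv(bundle$equity, "equity_table.csv")
  if (!is.null(bundle$or_tables)) {
    for (oc in names(bundle$or_tables)) {
      emit_csv(bundle$or_tables[[oc]], paste0("or_table_", oc, ".csv"))
    }
  }
  if (!is.null(bundle$max_gaps)) emit_csv(bundle$max_gaps, "max_gaps.csv")
  jp <- file.path(dir, "bundle.json")
  json_part <- list(composition = bundle$composition, equity = bundle$equity,
                    max_gaps = bundle$max_gaps,
                    or_tables = bundle$or_tables)
  jsonlite::write_json(json_part[!vapply(json_part, is.null, TRUE)], jp,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pp <- file.path(dir, "provenance.json")
  jsonlite::write_json(bundle$provenance, pp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp, pp))
}
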